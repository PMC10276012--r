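#' Digitized swimming trajectory
#'
#' Container for one recorded swim: apex positions over time plus optional
#' bell height/diameter series, the water temperature, and taxon labels.
#' Units are centimetres and seconds throughout (the scale at which medusae
#' are digitized); SI conversion happens only inside [reynolds_series()].
#'
#' @param t numeric vector of timestamps (s), strictly increasing, length >= 2.
#' @param x,y apex coordinates (cm), same length as `t`.
#' @param h optional bell height series (cm), positive where not `NA`.
#' @param D optional bell diameter series (cm), positive where not `NA`.
#' @param temperature water temperature (degrees C); default 20.
#' @param species,individual labels carried through all outputs.
#'
#' @return An object of class `"trajectory"`: a list with the fields above.
#' @seealso [simulate_swimmer()], [kinematics()], [write_trajectory_csv()]
#' @export
trajectory <- function(t, x, y, h = NULL, D = NULL, temperature = 20,
                       species = "unknown", individual = "1") {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n < 2L) stop_invalid("a trajectory needs at least 2 frames")
  if (length(x) != n || length(y) != n)
    stop_invalid("t, x, y must have equal length")
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop_invalid("timestamps must be finite and strictly increasing")
  for (nm in c("h", "D")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n) stop_invalid("'", nm, "' must match the number of frames")
      if (any(v[!is.na(v)] <= 0)) stop_invalid("'", nm, "' must be positive where present")
    }
  }
  assert_scalar_num(temperature, "temperature")
  temperature <- as.numeric(temperature)
  structure(list(t = t, x = x, y = y,
                 h = if (is.null(h)) NULL else as.numeric(h),
                 D = if (is.null(D)) NULL else as.numeric(D),
                 temperature = temperature,
                 species = as.character(species),
                 individual = as.character(individual)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s / %s: %d frames, %.3f-%.3f s, %s, %.1f degC\n",
              x$species, x$individual, length(x$t), x$t[1], x$t[length(x$t)],
              if (is.null(x$D)) "no bell series" else "with bell series",
              x$temperature))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  n <- length(x$t)
  data.frame(t_s = x$t, x_cm = x$x, y_cm = x$y,
             h_cm = if (is.null(x$h)) rep(NA_real_, n) else x$h,
             d_cm = if (is.null(x$D)) rep(NA_real_, n) else x$D,
             temp_c = rep(x$temperature, n),
             species = rep(x$species, n),
             individual = rep(x$individual, n))
}

#' Read and write trajectory CSV files
#'
#' Tidy CSV with unit-suffixed columns
#' `t_s, x_cm, y_cm, h_cm, d_cm, temp_c, species, individual` (the schema the
#' synthetic generator writes).  Values round-trip at full double precision.
#'
#' @param traj a [trajectory()] object.
#' @param path file path.
#' @return `read_trajectory_csv()` returns a [trajectory()];
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop_invalid("trajectory CSV must contain columns ", paste(need, collapse = ", "))
  opt <- function(col) if (col %in% names(df) && !all(is.na(df[[col]]))) df[[col]] else NULL
  trajectory(t = df$t_s, x = df$x_cm, y = df$y_cm,
             h = opt("h_cm"), D = opt("d_cm"),
             temperature = if ("temp_c" %in% names(df)) df$temp_c[1] else 20,
             species = if ("species" %in% names(df)) df$species[1] else "unknown",
             individual = if ("individual" %in% names(df)) df$individual[1] else "1")
}

#' Write or read generator ground truth as YAML
#'
#' Sidecar files holding the [swimmer_params()] used to generate a synthetic
#' sequence, so recovery tests can compare against the truth.
#'
#' @param params a [swimmer_params()] object.
#' @param path file path.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  do.call(swimmer_params, yaml::read_yaml(path))
}
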