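(Linuche_unguiculata:0.9,(((Sanderia_malayensis:0.25,(Chrysaora_quinquecirrha:0.12,(Chrysaora_plocamia:0.08,(Chrysaora_pacifica:0.06,Chrysaora_lactea:0.06):0.03):0.04):0.09):0.35,Cyanea_capillata:0.55):0.08,((Aurelia_solida:0.1,Aurelia_coerulea:0.1):0.4,(((Stomolophus_meleagris:0.15,Rhopilema_esculentum:0.16):0.1,(Lychnorhiza_lucerna:0.22,Catostylus_mosaicus:0.21):0.08):0.06,(Cotylorhiza_tuberculata:0.3,((Phyllorhiza_punctata:0.12,Mastigias_papua:0.11):0.08,Thysanostoma_thysanura:0.2):0.07):0.05):0.2):0.07):0.25);
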