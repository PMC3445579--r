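taxon,specimen_id,gape_angle_deg,prey_depth_fraction,mandible_length_cm
Metriorhynchus superciliosus,NHMUK PV R3016,11,0.08,88
"""Metriorhynchus"" brachyrhynchus",NHMUK PV R3804,10,0.07,82.3
Mr Leeds' specimen,GLAHM V972,15,0.13,67
Geosaurus giganteus,NHMUK PV OR37020,16,0.13,52
Dakosaurus maximus,SMNS 82043,19,0.15,87.5
Dakosaurus andiniensis,see Gasparini et al.,23,0.19,80
Plesiosuchus manselii,NHMUK PV R1089,24,0.21,132.2
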