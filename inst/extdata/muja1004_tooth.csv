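tooth_id,taxon,crown_apicobasal_mm,crown_mesiodistal_basal_mm,crown_labiolingual_basal_mm,denticle_length_um,denticle_height_um,denticle_width_um,mesial_count,mesial_span_mm,distal_count,distal_span_mm,provenance
MUJA-1004,cf. Plesiosuchus manselii,10.3,4.9,4.2,150,120,200,9,1,6,1,crown and density values printed; denticle dimensions synthetic microziphodont placeholders
NHMUK PV OR35766,Dakosaurus maximus,NA,NA,NA,425,330,675,NA,NA,NA,NA,printed denticle maxima
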