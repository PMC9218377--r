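trait,category,proportion_pct
glume_color,sienna,18.2
glume_color,mahogany,1.2
glume_color,red,75.7
glume_color,black,5.0
leaf_midrib_color,pale_green,29.6
leaf_midrib_color,white,70.4
grain_color,white,16.5
grain_color,yellow,18.8
grain_color,red,27.3
grain_color,brown,35.4
grain_color,buff,2.0
inflorescence_compactness,compact,20.6
inflorescence_compactness,semi_compact,30.7
inflorescence_compactness,loose,48.4
inflorescence_compactness,semi_loose,0.3
inflorescence_shape,erect,1.7
inflorescence_shape,drooping,44.9
inflorescence_shape,elliptic,42.0
inflorescence_shape,oval,11.3
glume_covering,cover_25,60.0
glume_covering,cover_50,32.2
glume_covering,cover_75,5.5
glume_covering,cover_100,1.4
glume_covering,longer_than_grain,0.9
awns,present,7.5
awns,absent,92.5
agronomic_score,poor,6.3
agronomic_score,average,31.4
agronomic_score,good,62.4
panicle_exsertion,slightly_exserted,5.5
panicle_exsertion,exserted,50.5
panicle_exsertion,well_exserted,35.9
panicle_exsertion,recurved,8.2
stay_green,very_slightly_senescent,0.5
stay_green,slightly_senescent,19.7
stay_green,intermediate,38.8
stay_green,mostly_senescent,31.4
stay_green,completely_senescent,9.7
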