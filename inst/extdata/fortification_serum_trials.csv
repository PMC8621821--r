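label,food,country,n,duration,serum_increase_nmol_l,notes
Keane 1998,milk,Ireland,51,12 months,15,200 IU/day
McKenna 1995,milk,Ireland,102,4 months,16,480 IU/L
Khadgawat 2013 (600 IU),milk,India,713,12 weeks,12.1,school children
Khadgawat 2013 (1000 IU),milk,India,713,12 weeks,16.9,school children
Jaaskelainen 2017,milk products and fat spreads,Finland,6134,11 years,17.9,population pre-post; mean of sexes
Kruger 2019,milk powder,Malaysia,133,12 months,12.2,600 IU/day
Gasparri 2019,yoghurt,various,665,8-16 weeks,31,meta-analysis
Nikooyeh 2016,bread,Iran,90,8 weeks,48.3,1000 IU/50 g
Itkonen 2016,bread,Finland,41,8 weeks,7,1040 IU/day
Biancuzzo 2010 (D3),orange juice,USA,105,11 weeks,12.3,1000 IU/237 mL
Madsen 2013,milk and bread,Denmark,201,6 months,19,median 376 IU/day
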