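"wl","irradiance"
300,0.051165
310,0.083345
320,0.131157
330,0.200043
340,0.296567
350,0.42844
360,0.604509
370,0.834699
380,1.12992
390,1.50191
400,1.96314
410,2.52653
420,3.20531
430,4.0128
440,4.96217
450,6.06624
460,7.33727
470,8.7868
480,10.4254
490,12.2628
500,14.3072
510,16.5658
520,19.0444
530,21.7475
540,24.6778
550,27.8371
560,31.2256
570,34.8419
580,38.6836
590,42.747
600,47.0271
610,51.5179
620,56.2123
630,61.1025
640,66.1796
650,71.4342
660,76.8562
670,82.435
680,88.1595
690,94.0184
700,100
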