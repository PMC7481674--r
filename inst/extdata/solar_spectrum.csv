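wavelength_nm,irradiance_w_m2_nm
400,1.605
410,1.693
420,1.703
430,1.639
440,1.810
450,2.006
460,2.066
470,2.033
480,2.074
490,1.950
500,1.942
510,1.882
520,1.833
530,1.842
540,1.783
550,1.844
560,1.803
570,1.794
580,1.787
590,1.736
600,1.748
610,1.712
620,1.715
630,1.666
640,1.602
650,1.589
660,1.568
670,1.545
680,1.508
690,1.440
700,1.415
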