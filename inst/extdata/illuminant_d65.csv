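wl,energy
300,0.034
310,3.294
320,20.236
330,37.054
340,39.949
350,44.911
360,46.638
370,52.089
380,49.975
390,54.648
400,82.755
410,91.486
420,93.432
430,86.682
440,104.865
450,117.008
460,117.812
470,114.861
480,115.923
490,108.811
500,109.354
510,107.802
520,104.790
530,107.689
540,104.405
550,104.046
560,100.000
570,96.334
580,95.788
590,88.686
600,90.006
610,89.599
620,87.699
630,83.289
640,83.699
650,80.027
660,80.215
670,82.278
680,78.284
690,69.721
700,71.609
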