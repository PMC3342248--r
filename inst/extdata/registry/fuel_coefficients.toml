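# Fine-fuel planar-intercept coefficients by timelag class.
# qmd2: squared quadratic-mean particle diameter (cm^2); spgr: specific
# gravity; angle: nonhorizontal-angle correction; slope: slope correction
# (flat-plot default). Values are standard western mixed-conifer defaults.
qmd2_cm2_1h = 0.097
qmd2_cm2_10h = 1.86
qmd2_cm2_100h = 17.81
spgr_1h = 0.48
spgr_10h = 0.48
spgr_100h = 0.40
angle_1h = 1.13
angle_10h = 1.13
angle_100h = 1.00
slope = 1.00
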