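# Demonstration registry

A complete, internally consistent registry file set for the Sierra Nevada
mixed-conifer species pool: allometric equations, proxy substitution and
capping rules, decay-class wood densities, fine-fuel coefficients and
shrub demography proxies.

The allometric coefficients and wood densities are **plausible
demonstration values, not authoritative published equations**. They have
realistic magnitudes and the correct structural relationships (component
routing, diameter ranges, capping thresholds at 110 cm for *Abies* and
162 cm for *Pseudotsuga* branch/foliage), so every code path is
exercised, but analyses of real census data must replace
`equations.csv`, `substitutions.csv` and `decay_densities.csv` with the
equations selected for the study area. The file schemas are documented
in `?read_equations`, `?read_substitutions` and `?read_decay_densities`.
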