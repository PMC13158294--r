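# Regenerates the packaged synthetic study fixture (seed 1 of the built-in
# wheat heat-stress truth).  Run from the package root.
library(polarnet)
study <- generate_study(design = study_design(), truth = wheat_heat_truth(), seed = 1)
paths <- write_fixtures(study, file.path("inst", "extdata", "wheat_heat_study"))
print(paths)
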