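# Generates the packaged default scoring matrix from a synthetic calibration
# study (one vehicle arm + four directional control arms, 100 wells each)
# at a fixed seed. Run from the repository root:
#   Rscript data-raw/default-matrix.R
library(cthazard)
m <- calibrate_scoring_matrix(seed = 20181211, n_wells = 100)
print(m)
write_scoring_matrix(m, file.path("inst", "extdata", "default_matrix.yaml"))
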