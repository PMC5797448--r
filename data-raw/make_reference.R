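# Builds the shipped synthetic reference pattern:
# 8 simulated datasets (48 samples each, noise SD 0.5, default two-arm phase
# architecture), meta-analyzed on the Fisher-z scale.
# Run from the package root: Rscript data-raw/make_reference.R
pkgload::load_all(".", quiet = TRUE)
panel <- simulate_reference_panel(8, n_samples = 48, noise_sd = 0.5,
                                  seed = 20260921)
ref <- meta_reference(lapply(panel, function(d) correlation_vector(d$expr)))
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_reference(ref, "inst/extdata/reference_synthetic.csv")
cat("wrote", length(ref$rho), "pairs; rho range",
    paste(round(range(ref$rho), 3), collapse = " .. "), "\n")
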