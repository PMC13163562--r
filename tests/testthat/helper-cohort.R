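# Build a minimal valid examination table; override any column per row.
make_exams <- function(n = 3, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    age_years = 60,
    weight_kg = 72.7,
    height_cm = 168.15,
    lat_dim_a_cm = 34.06,
    ap_dim_b_cm = 25.43,
    topo_ctdivol_mgy = 0.14,
    topo_dlp_mgycm = 5.15,
    topo_length_mm = 386.55,
    scan_ctdivol_mgy = 1.33,
    scan_dlp_mgycm = 50.35,
    scan_length_mm = 403
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Brute-force two-sided permutation p-value; independent oracle for the
# normality-gated two-sample comparison.
perm_pvalue <- function(x, y, B = 10000,
                        stat = function(a, b) mean(a) - mean(b)) {
  z <- c(x, y)
  n <- length(x)
  obs <- stat(x, y)
  null_stats <- vapply(seq_len(B), function(i) {
    idx <- sample.int(length(z), n)
    stat(z[idx], z[-idx])
  }, numeric(1))
  center <- mean(null_stats)
  (1 + sum(abs(null_stats - center) >= abs(obs - center) - 1e-12)) / (B + 1)
}
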