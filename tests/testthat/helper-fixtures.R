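# Shared fixtures: small parameter sets and a physiology stub with an
# adjustable bulk flow for limit checks.

par_rat <- function() raf_params("rat")

par_custom <- function(alpha = 0.4, beta = 1.4, gamma = 1900, sigma = 1000,
                       species = "rat", mode = "RAF") {
  scaling_params(alpha, beta, gamma, sigma, species = species, mode = mode)
}

phys_with_k <- function(k, base = "rat") {
  p <- species_physiology(base)
  p$cl_bulkflow <- k
  p
}

toy_compounds <- function() {
  data.frame(
    compound_id = c("free", "mdr1", "dual"),
    logD = c(2.5, 1.0, 0.2),
    MW = c(250, 420, 510),
    ER_MDR1 = c(0.9, 15, 8),
    ER_BCRP = c(1.0, 1.2, 4),
    stringsAsFactors = FALSE)
}
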