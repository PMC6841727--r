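# Shared fixture builders. Everything is generated in code at test time.

# A small summary-statistics file on disk, returning its path.
write_ma_fixture <- function(lines, file = tempfile(fileext = ".ma")) {
  writeLines(lines, file)
  file
}

ma_header <- "SNP A1 A2 freq b se p N"

# A tiny, fully in-memory study: panel + phenotype + GWAS + exact stats.
tiny_study <- function(n = 400, p = 60, h2 = 0.5, causal = c(2, 4, 2),
                       rho = 0.8, block = 20, seed = 42) {
  set.seed(seed)
  geno <- simulate_genotypes(n, p, block_size = block, rho = rho)
  eff <- simulate_effects(p, architecture_spec(counts = causal))
  y <- simulate_phenotype(geno, eff$beta, h2)
  y <- as.numeric(scale(y))
  list(geno = geno, y = y, beta = eff$beta, causal = eff$causal,
       gwas = run_gwas(geno, y))
}
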