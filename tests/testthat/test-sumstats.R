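test_that("read_ma parses well-formed files and enforces the contract", {
  path <- write_ma_fixture(c(
    ma_header,
    "rs1 a g 0.3 0.12 0.05 0.02 1000",
    "rs2 C T 0.6 -0.04 0.03 0.2 1500"))
  ds <- read_ma(path)
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$A1, c("A", "C"))          # upper-cased
  expect_equal(ds$b, c(0.12, -0.04))
  expect_equal(ds$n, c(1000, 1500))

  # missing required column
  bad <- write_ma_fixture(c("SNP A1 A2 freq b p N",
                            "rs1 A G 0.3 0.1 0.5 100"))
  expect_error(read_ma(bad), "SE")

  # invariant-violating rows are rejected with a warning, not an error
  mixed <- write_ma_fixture(c(
    ma_header,
    "rs1 A G 0.3 0.1 0 0.5 1000",       # se = 0
    "rs2 A G 0.3 0.1 0.05 0.5 1000",
    "rs3 A G 0.3 xx 0.05 0.5 1000"))    # non-numeric b
  expect_warning(ds2 <- read_ma(mixed), "2 row")
  expect_equal(ds2$snp_id, "rs2")

  dup <- write_ma_fixture(c(ma_header,
                            "rs1 A G 0.3 0.1 0.05 0.5 1000",
                            "rs1 A G 0.4 0.2 0.05 0.5 1000"))
  expect_error(suppressWarnings(read_ma(dup)), "duplicate")
})

test_that("qc_filter applies MAF, strand-ambiguity, n-percentile and region rules", {
  ds <- summary_dataset(
    snp_id = c("s1", "s2", "s3", "s4"),
    A1 = c("A", "A", "C", "A"), A2 = c("T", "G", "G", "G"),
    freq = c(0.3, 0.005, 0.3, 0.3), b = rep(0.1, 4), se = rep(0.05, 4),
    n = rep(1000, 4))
  out <- qc_filter(ds, qc_config(maf_min = 0.01, drop_ambiguous = TRUE,
                                 n_lower_pct = 0, n_upper_pct = 100))
  expect_equal(out$snp_id, "s4")   # s1 ambiguous A/T, s2 rare, s3 ambiguous C/G
  expect_equal(unname(attr(out, "qc_counts")[c("maf", "ambiguous")]),
               c(1L, 2L))

  # percentile rule: n = 1..100 with 5/95 keeps exactly 6..95
  ds_n <- summary_dataset(snp_id = paste0("v", 1:100), A1 = "A", A2 = "G",
                          freq = 0.4, b = 0, se = 0.1, n = 1:100)
  out_n <- qc_filter(ds_n, qc_config(maf_min = 0, drop_ambiguous = FALSE,
                                     n_lower_pct = 5, n_upper_pct = 95))
  expect_equal(sort(out_n$n), 6:95)
  expect_equal(unname(attr(out_n, "qc_counts")["n_percentile"]), 10L)

  # no active filters -> identity
  out_id <- qc_filter(ds_n, qc_config(maf_min = 0, drop_ambiguous = FALSE,
                                      n_lower_pct = 0, n_upper_pct = 100))
  expect_equal(out_id$snp_id, ds_n$snp_id)

  # region exclusion removes inside [start, end) on the right chromosome
  ds_r <- summary_dataset(snp_id = c("a", "b", "c"), A1 = "A", A2 = "G",
                          freq = 0.4, b = 0, se = 0.1, n = 100,
                          chrom = c("6", "6", "7"), bp = c(100, 500, 100))
  out_r <- qc_filter(ds_r, qc_config(maf_min = 0, drop_ambiguous = FALSE,
                                     n_lower_pct = 0, n_upper_pct = 100,
                                     exclude_regions = data.frame(
                                       chrom = "6", start = 50, end = 500)))
  expect_equal(out_r$snp_id, c("b", "c"))   # end is half-open

  expect_error(qc_filter(ds_n, qc_config(maf_min = 0.49)), "every SNP")
})

test_that("qc_filter is idempotent in the near-constant-n regime", {
  set.seed(1)
  n_vals <- c(rep(50000, 97), round(runif(3, 1000, 20000)))
  ds <- summary_dataset(snp_id = paste0("v", 1:100), A1 = "A", A2 = "G",
                        freq = runif(100, 0.05, 0.5), b = 0, se = 0.1,
                        n = n_vals)
  cfg <- qc_config(n_lower_pct = 2.5, n_upper_pct = 95)
  once <- qc_filter(ds, cfg)
  twice <- qc_filter(once, cfg)
  expect_equal(twice$snp_id, once$snp_id)
})

test_that("align_to_reference flips, keeps and drops correctly and is an involution", {
  ds <- summary_dataset(snp_id = c("s1", "s2", "s3", "s4"),
                        A1 = c("G", "A", "A", "A"),
                        A2 = c("A", "G", "G", "G"),
                        freq = c(0.7, 0.3, 0.3, 0.3),
                        b = c(0.1, 0.2, 0.3, 0.4), se = 0.05, n = 1000)
  ref <- data.frame(snp_id = c("s1", "s2", "s3"),
                    A1 = c("A", "A", "C"), A2 = c("G", "G", "T"),
                    freq = c(0.3, 0.3, 0.5))
  out <- align_to_reference(ds, ref)
  # s1 flipped, s2 unchanged, s3 allele mismatch dropped, s4 not in ref
  expect_equal(out$snp_id, c("s1", "s2"))
  expect_equal(out$b, c(-0.1, 0.2))
  expect_equal(out$freq, c(0.3, 0.3))
  expect_equal(out$A1, c("A", "A"))
  cts <- attr(out, "align_counts")
  expect_equal(unname(cts[c("missing", "flipped", "mismatch")]),
               c(1L, 1L, 1L))

  # involution: aligning to the swapped reference recovers the original
  # effects relative to each SNP's original allele coding (s1 was stored
  # against G, s2 against A, so s2 reads negated against the G-coded ref_sw)
  ref_sw <- data.frame(snp_id = ref$snp_id, A1 = ref$A2, A2 = ref$A1,
                       freq = 1 - ref$freq)
  back <- align_to_reference(out, ref_sw)
  expect_equal(back$b, c(0.1, -0.2))
  expect_equal(back$A1, c("G", "G"))
  expect_equal(back$freq, c(0.7, 0.7))

  # frequency mismatch warning / optional drop
  ds_f <- summary_dataset(snp_id = "s1", A1 = "A", A2 = "G", freq = 0.9,
                          b = 0.1, se = 0.05, n = 100)
  ref_f <- data.frame(snp_id = "s1", A1 = "A", A2 = "G", freq = 0.3)
  expect_warning(align_to_reference(ds_f, ref_f), "freq")
  expect_error(suppressWarnings(
    align_to_reference(ds_f, ref_f, drop_freq_mismatch = TRUE)))

  expect_error(align_to_reference(ds, ref[0, , drop = FALSE]))
})

test_that("reconstruct_D matches the closed form and the in-sample oracle", {
  ds <- summary_dataset(snp_id = c("a", "b", "c"), A1 = "A", A2 = "G",
                        freq = 0.3, b = c(0.1, 0, 0.1),
                        se = c(0.05, 0.05, 0.01), n = 1000)
  D <- reconstruct_D(ds)
  expect_equal(unname(D[1]), 1 / (0.05^2 + 0.1^2 / 1000))  # ~398.406
  expect_equal(unname(D[1]), 398.4064, tolerance = 1e-6)
  expect_equal(unname(D[2]), 400)                           # b = 0 case
  expect_equal(unname(reconstruct_D(ds, scaled = TRUE)), rep(1000, 3))

  # against the true diagonal of X'X from this package's own GWAS
  st <- tiny_study(n = 800, p = 40)
  Xc <- centred_dosage(st$geno)
  D_hat <- reconstruct_D(st$gwas)
  expect_lt(max(abs(D_hat - colSums(Xc^2)) / colSums(Xc^2)), 0.01)
})

test_that("reconstruct_sufficient builds X'y, y'y and n_bar as documented", {
  ds <- summary_dataset(snp_id = c("a", "b", "c"), A1 = "A", A2 = "G",
                        freq = 0.3, b = c(0.1, 0, -0.2), se = 0.05,
                        n = c(100, 100, 200))
  st <- reconstruct_sufficient(ds)
  expect_equal(st$Xty, unname(reconstruct_D(ds)) * ds$b)
  expect_equal(st$n_bar, 100)
  expect_equal(st$yty, 100)   # standardised-phenotype convention
  ds0 <- summary_dataset(snp_id = c("a", "b"), A1 = "A", A2 = "G",
                         freq = 0.3, b = 0, se = 0.05, n = 100)
  expect_equal(reconstruct_sufficient(ds0)$Xty, c(0, 0))

  # end-to-end: reconstructed X'y close to the directly computed one
  sty <- tiny_study(n = 1000, p = 50)
  rec <- reconstruct_sufficient(sty$gwas)
  Xc <- centred_dosage(sty$geno)
  direct <- drop(crossprod(Xc, sty$y - mean(sty$y)))
  expect_lt(max(abs(rec$Xty - direct) / pmax(abs(direct), 1)), 0.01)
})

test_that("write_ma round-trips a dataset", {
  ds <- tiny_study(n = 200, p = 10)$gwas
  path <- tempfile(fileext = ".ma")
  write_ma(ds, path)
  back <- read_ma(path)
  expect_equal(back$snp_id, ds$snp_id)
  expect_equal(back$b, ds$b, tolerance = 1e-12)
})
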