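test_that("bin_hits places hits by floor(start/width) and conserves totals", {
  b <- bin_hits(c(100, 9999, 10001), 10000, 100000)
  expect_identical(nrow(b), 10L)
  expect_identical(b$count[1:2], c(2L, 1L))
  expect_identical(sum(b$count), 3L)

  empty <- bin_hits(integer(0), 50, 5300)
  expect_identical(nrow(empty), as.integer(ceiling(5300 / 50)))
  expect_true(all(empty$count == 0L))

  expect_error(bin_hits(c(10, 200), 50, 100), "outside")

  set.seed(41)
  starts <- sample(0:9999, 500, replace = TRUE)
  b2 <- bin_hits(starts, 128, 10000)
  expect_identical(sum(b2$count), 500L)
})

test_that("a planted hotspot bin is the argmax of the bin map", {
  set.seed(42)
  bg <- sample(0:19999, 40)
  hot <- 7000 + sample(0:999, 50, replace = TRUE)  # 50x enrichment in bin 7
  b <- bin_hits(c(bg, hot), 1000, 20000)
  expect_identical(which.max(b$count) - 1L, 7L)
})

test_that("plasmid_fraction follows the all-spacer ratio rule", {
  expect_equal(plasmid_fraction(91, 9), 0.09)
  expect_equal(plasmid_fraction(0, 5), 1.0)
  expect_error(plasmid_fraction(0, 0), "undefined")
  expect_error(plasmid_fraction(-1, 5), "negative")
})

test_that("dedup rule matters: all-spacer vs unique-spacer ratios differ", {
  # 10 chromosomal singletons + 1 plasmid spacer duplicated 10x
  hits <- data.frame(source = c(rep("chromosome", 10), "plasmid"))
  w <- c(rep(1, 10), 10)
  all_counts <- classify_sources(hits, w)
  uniq_counts <- classify_sources(hits)
  f_all <- plasmid_fraction(all_counts[["chromosome"]], all_counts[["plasmid"]])
  f_uniq <- plasmid_fraction(uniq_counts[["chromosome"]], uniq_counts[["plasmid"]])
  expect_equal(f_all, 0.5)
  expect_equal(f_uniq, 1 / 11)
})

test_that("molar_excess is plain proportional arithmetic", {
  expect_equal(molar_excess(4641652, 5300, 40), 4641652 / (40 * 5300))
  expect_equal(round(molar_excess(4641652, 5300, 40), 1), 21.9)
  expect_equal(molar_excess(1000, 1000, 1), 1.0)
  expect_equal(molar_excess(4641652, 5300, 80),
               molar_excess(4641652, 5300, 40) / 2)
  expect_error(molar_excess(0, 5300, 40), "positive")
})

test_that("bias_summary computes neutral share and odds-ratio index", {
  refs <- tiny_refs(seed = 43)   # 2000 bp chromosome, 400 bp plasmid, c=40
  s <- (40 * 400) / (40 * 400 + 2000)
  bs <- bias_summary(n_chromosome = 100, n_plasmid = round(100 * s / (1 - s)),
                     refs = refs)
  expect_equal(bs$neutral_plasmid_share, s)
  expect_equal(bs$bias_index, 1.0, tolerance = 0.01)

  # E. coli scale: neutral plasmid share for g=4641652, p=5300, c=40
  s2 <- (40 * 5300) / (40 * 5300 + 4641652)
  expect_equal(round(s2, 4), 0.0437)

  # degenerate fractions flag and collapse the index
  expect_identical(bias_summary(5, 0, refs)$bias_index, 0)
  expect_true(is.infinite(bias_summary(0, 5, refs)$bias_index))
})

test_that("neutral planting yields a bias index near 1 (binomial oracle)", {
  refs <- tiny_refs(seed = 44)
  s <- (refs$plasmid_copy_number * nchar(refs$plasmid)) /
    (refs$plasmid_copy_number * nchar(refs$plasmid) + nchar(refs$chromosome))
  set.seed(45)
  n <- 4000
  n_p <- stats::rbinom(1, n, s)
  bs <- bias_summary(n - n_p, n_p, refs)
  # 3 SE on the log-odds scale
  se_logodds <- sqrt(1 / (n * s * (1 - s)))
  expect_lt(abs(log(bs$bias_index)), 3 * se_logodds)
})

test_that("build_pam_matrix counts, information bounds and consensus", {
  pm <- build_pam_matrix(rep("AAG", 100))
  expect_identical(pm$consensus, "AAG")
  expect_equal(pm$information, c(2, 2, 2))
  expect_equal(unname(colSums(pm$counts)), rep(100, 3))

  # uniform column has 0 bits
  pm2 <- build_pam_matrix(c("A", "C", "G", "T"))
  expect_equal(pm2$information, 0)

  expect_error(build_pam_matrix(c("AAG", "AA")), "unequal")
  expect_error(build_pam_matrix(character(0)), "no PAM")

  # information lies in [0,2]; pseudocount never increases it
  set.seed(46)
  for (i in 1:10) {
    pams <- replicate(30, rand_dna(3))
    a <- build_pam_matrix(pams)
    b <- build_pam_matrix(pams, pseudocount = 1)
    expect_true(all(a$information >= -1e-12 & a$information <= 2 + 1e-12))
    expect_true(all(b$information <= a$information + 1e-12))
  }
})

test_that("planted PAM bias is recovered as an AAG consensus", {
  cfg <- quick_sim(seed = 47, n_events = 150, parental = 0, w = 500)
  sim <- simulate_run(cfg)
  parsed <- parse_reads(sim$reads, sim$refgen$model)
  tal <- collapse_duplicates(parsed$spacers$spacer)
  hits <- map_spacers(tal$tally$spacer, sim$refgen$refs)
  pams <- hits$pam[hits$source %in% c("chromosome", "plasmid")]
  expect_identical(build_pam_matrix(pams)$consensus, "AAG")
})

test_that("count_pam_sites matches a brute-force substring oracle", {
  expect_identical(count_pam_sites("AAGTTAAG", circular = FALSE,
                                   strands = "forward"), 2L)
  # CTT never occurs on the forward strand here
  expect_identical(count_pam_sites("AAGTTAAG", circular = FALSE), 2L)

  brute <- function(s, motif, circular, both) {
    L <- nchar(s); w <- nchar(motif)
    ext <- if (circular) paste0(s, substr(s, 1, w - 1)) else s
    hits <- 0L
    pats <- if (both) c(motif, revcomp(motif)) else motif
    for (p in pats) {
      for (i in seq_len(nchar(ext) - w + 1)) {
        if (substr(ext, i, i + w - 1) == p) hits <- hits + 1L
      }
    }
    hits
  }
  set.seed(48)
  for (i in 1:12) {
    s <- rand_dna(200)
    for (circ in c(TRUE, FALSE)) {
      expect_identical(count_pam_sites(s, "AAG", circ, "both"),
                       brute(s, "AAG", circ, TRUE))
      expect_identical(count_pam_sites(s, "AAG", circ, "forward"),
                       brute(s, "AAG", circ, FALSE))
    }
  }
  # wrap-spanning site is counted only when circular
  s2 <- paste0("AG", strrep("C", 30), "A")
  expect_identical(count_pam_sites(s2, "AAG", circular = TRUE,
                                   strands = "forward"), 1L)
  expect_identical(count_pam_sites(s2, "AAG", circular = FALSE,
                                   strands = "forward"), 0L)
})
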