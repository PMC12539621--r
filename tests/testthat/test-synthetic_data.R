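test_that("generator is fully deterministic under a fixed seed", {
  cfg <- quick_sim(seed = 9, n_events = 20)
  a <- simulate_run(cfg)
  b <- simulate_run(cfg)
  expect_identical(a$refgen$refs$chromosome, b$refgen$refs$chromosome)
  expect_identical(a$refgen$refs$plasmid, b$refgen$refs$plasmid)
  expect_identical(a$events, b$events)
  expect_identical(a$reads$sequence, b$reads$sequence)
})

test_that("references have exact lengths and exactly one embedded cassette", {
  cfg <- quick_sim(seed = 2)
  rg <- generate_references(cfg)
  expect_identical(nchar(rg$refs$chromosome), cfg$chromosome_length)
  expect_identical(nchar(rg$refs$plasmid), cfg$plasmid_length)
  cassette <- paste0(rg$template$upstream, rg$template$repeat_seq,
                     rg$template$downstream)
  expect_identical(
    Biostrings::countPattern(cassette,
                             Biostrings::DNAString(rg$refs$chromosome)), 1L)
  expect_identical(substr(rg$refs$chromosome, rg$cassette_start + 1,
                          rg$cassette_start + nchar(cassette)), cassette)
})

test_that("gc_content = 1 makes all non-cassette bases G/C", {
  cfg <- sim_config(seed = 4, chromosome_length = 5000L,
                    plasmid_length = 500L, gc_content = 1)
  rg <- generate_references(cfg)
  expect_false(grepl("[AT]", rg$refs$plasmid))
  cassette <- paste0(rg$template$upstream, rg$template$repeat_seq,
                     rg$template$downstream)
  flanks <- paste0(substr(rg$refs$chromosome, 1, rg$cassette_start),
                   substr(rg$refs$chromosome,
                          rg$cassette_start + nchar(cassette) + 1,
                          nchar(rg$refs$chromosome)))
  # downstream stub is random too, so only check outside the cassette
  expect_false(grepl("[AT]", flanks))
})

test_that("plasmid_source_prob is honoured: edge case and binomial recovery", {
  cfg0 <- quick_sim(seed = 5, n_events = 30, pi = 0)
  ev0 <- plant_events(generate_references(cfg0), cfg0)
  expect_true(all(ev0$source == "chromosome"))

  cfg <- sim_config(seed = 6, n_events = 2000L, plasmid_source_prob = 0.64,
                    chromosome_length = 30000L, plasmid_length = 3000L,
                    pam_bias = 1)
  ev <- plant_events(generate_references(cfg), cfg)
  se <- sqrt(0.64 * 0.36 / 2000)
  expect_lt(abs(mean(ev$source == "plasmid") - 0.64), 3 * se)
})

test_that("strong pam_bias plants essentially only AAG PAMs", {
  cfg <- quick_sim(seed = 7, n_events = 150, w = 1e9)
  ev <- plant_events(generate_references(cfg), cfg)
  expect_true(all(ev$pam == "AAG"))
})

test_that("event invariants hold: spacer and PAM re-extractable from references", {
  cfg <- quick_sim(seed = 8, n_events = 60, w = 5)
  rg <- generate_references(cfg)
  ev <- plant_events(rg, cfg)
  m <- rg$model$expected_spacer_length
  for (i in seq_len(nrow(ev))) {
    r <- ref_get_test(rg$refs, ev$source[i])
    expect_identical(
      circular_window(r$seq, ev$start[i], m, ev$strand[i], r$circular),
      ev$spacer[i])
  }
  expect_true(all(ev$duplication_count >= 1))
})

test_that("error-free reads equal their template up to orientation", {
  cfg <- quick_sim(seed = 10, n_events = 15, parental = 0)
  sim <- simulate_run(cfg)
  tpl <- sim$refgen$template
  expected <- paste0(tpl$upstream, tpl$repeat_seq, sim$events$spacer,
                     tpl$repeat_seq, tpl$downstream)
  expected <- rep(expected, sim$events$duplication_count)
  got <- sim$reads$sequence
  norm <- ifelse(got == expected | revcomp(got) == expected, TRUE, FALSE)
  expect_true(all(norm))
  # both orientations actually occur
  expect_true(any(got != expected) && any(got == expected))
})

test_that("parental_read_fraction = 1 yields a pool with no expansions", {
  cfg <- quick_sim(seed = 11, n_events = 10, parental = 1)
  sim <- simulate_run(cfg)
  parsed <- parse_reads(sim$reads, sim$refgen$model)
  expect_identical(nrow(parsed$spacers), 0L)
  expect_identical(parsed$counters$expanded, 0L)
})

test_that("mean per-read edit distance matches the configured error rate", {
  # total error rate 0.02/base; independent oracle: utils::adist vs template
  cfg <- quick_sim(seed = 12, n_events = 60, parental = 0,
                   error = c(0.01, 0.005, 0.005))
  sim <- simulate_run(cfg)
  tpl <- sim$refgen$template
  expected <- rep(paste0(tpl$upstream, tpl$repeat_seq, sim$events$spacer,
                         tpl$repeat_seq, tpl$downstream),
                  sim$events$duplication_count)
  got <- sim$reads$sequence
  # undo orientation by picking the closer of the two
  d <- vapply(seq_along(got), function(i) {
    min(utils::adist(got[i], expected[i]),
        utils::adist(revcomp(got[i]), expected[i]))
  }, numeric(1))
  mu <- 0.02 * mean(nchar(expected))
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 3 * se)
})

test_that("simulate_run writes the documented output files", {
  dir <- withr::local_tempdir()
  cfg <- quick_sim(seed = 13, n_events = 8)
  simulate_run(cfg, out_dir = dir)
  for (f in c("chromosome.fasta", "plasmid.fasta", "reads.fastq",
              "truth.tsv", "config.json")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(truth), 8L)
  expect_named(truth, c("event_id", "source", "start", "strand", "spacer",
                        "pam", "duplication_count"))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(plasmid_source_prob = 1.2), "in \\[0,1\\]")
  expect_error(sim_config(pam_bias = 0.5), ">= 1")
  expect_error(error_model(0.3, 0, 0), "0.2")
  expect_error(error_model(0.2, 0.2, 0.15), "0.5")
  expect_error(sim_config(n_events = 0))
})
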