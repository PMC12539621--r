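test_that("verbatim windows map back exactly on both strands", {
  refs <- tiny_refs(seed = 31)
  sp_plus <- circular_window(refs$plasmid, 100, 32, "+", TRUE)
  h <- map_spacer(sp_plus, refs)
  expect_identical(h$source, "plasmid")
  expect_identical(h$start, 100L)
  expect_identical(h$strand, "+")
  expect_identical(h$edit_distance, 0L)

  sp_minus <- circular_window(refs$chromosome, 500, 32, "-", TRUE)
  h2 <- map_spacer(sp_minus, refs)
  expect_identical(h2$source, "chromosome")
  expect_identical(h2$start, 500L)   # forward-strand window start
  expect_identical(h2$strand, "-")
})

test_that("mapping tolerates edits up to max_edits and wraps the origin", {
  refs <- tiny_refs(seed = 32)
  sp <- circular_window(refs$chromosome, 700, 32, "+", TRUE)
  mut <- sp
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  h <- map_spacer(mut, refs)
  expect_identical(h$source, "chromosome")
  expect_identical(h$start, 700L)
  expect_identical(h$edit_distance, 1L)

  # window spanning the origin of the circular plasmid
  L <- nchar(refs$plasmid)
  sp_wrap <- circular_window(refs$plasmid, L - 10, 32, "+", TRUE)
  hw <- map_spacer(sp_wrap, refs)
  expect_identical(hw$source, "plasmid")
  expect_identical(hw$start, L - 10L)
})

test_that("random spacers are unmapped; shared windows are ambiguous", {
  refs <- tiny_refs(seed = 33)
  set.seed(34)
  cats <- vapply(1:20, function(i) map_spacer(rand_dna(33), refs)$source,
                 character(1))
  expect_true(mean(cats == "unmapped") >= 0.9)

  # plant the same window in both replicons
  shared <- rand_dna(32, seed = 35)
  refs2 <- reference_set(
    paste0(substr(refs$chromosome, 1, 600), shared,
           substr(refs$chromosome, 633, nchar(refs$chromosome))),
    paste0(substr(refs$plasmid, 1, 50), shared,
           substr(refs$plasmid, 83, nchar(refs$plasmid))))
  ha <- map_spacer(shared, refs2)
  expect_identical(ha$source, "ambiguous")
  expect_identical(ha$pam, "")
  expect_gte(ha$n_equal_best, 2L)
})

test_that("within-replicon multi-mappers pick the lowest start and log multiplicity", {
  set.seed(36)
  dup <- rand_dna(32)
  filler <- function(n) rand_dna(n)
  chrom <- paste0(filler(100), dup, filler(200), dup, filler(1000))
  refs <- reference_set(chrom, filler(300))
  h <- map_spacer(dup, refs)
  expect_identical(h$source, "chromosome")
  expect_identical(h$start, 100L)
  expect_identical(h$n_equal_best, 2L)
})

test_that("PAM extraction matches the constructed -2..+1 window on both strands", {
  # protospacer starts at the G of ...TTAAGCCC... -> PAM "AAG"
  set.seed(37)
  left <- rand_dna(60)
  core <- "TTAAGCCC"
  right <- rand_dna(200)
  chrom <- paste0(left, core, right)
  start_g <- nchar(left) + 4L   # 0-based position of the G
  refs <- reference_set(chrom, rand_dna(100))
  spacer <- circular_window(chrom, start_g, 32, "+", TRUE)
  h <- map_spacer(spacer, refs)
  expect_identical(h$start, start_g)
  expect_identical(h$pam, "AAG")

  # the same physical site on the reverse-complemented chromosome gives
  # the same PAM on the minus strand (strand symmetry)
  chrom_rc <- revcomp(chrom)
  refs_rc <- reference_set(chrom_rc, rand_dna(100))
  h2 <- map_spacer(spacer, refs_rc)
  expect_identical(h2$strand, "-")
  expect_identical(h2$pam, "AAG")
  expect_identical(h2$start, nchar(chrom) - (start_g + 32L))

  # extract_pam errors on unmapped hits
  expect_error(extract_pam(data.frame(source = "unmapped", start = NA,
                                      strand = NA, spacer = "ACGT"), refs),
               "not mapped")
})

test_that("PAM wraps across the origin of a circular replicon", {
  set.seed(38)
  plas <- rand_dna(300)
  substr(plas, 299, 300) <- "AA"   # upstream bases of a protospacer at 0
  refs <- reference_set(rand_dna(2000), plas)
  spacer <- circular_window(plas, 0, 32, "+", TRUE)
  h <- map_spacer(spacer, refs)
  expect_identical(h$start, 0L)
  expect_identical(h$pam, paste0("AA", substr(plas, 1, 1)))
})

test_that("configurable 4-base PAM window is supported", {
  refs <- tiny_refs(seed = 39)
  sp <- circular_window(refs$chromosome, 900, 32, "+", TRUE)
  h <- map_spacer(sp, refs, pam_offset = -2L, pam_width = 4L)
  expect_identical(nchar(h$pam), 4L)
  expect_identical(substr(h$pam, 1, 3),
                   map_spacer(sp, refs)$pam)
})

test_that("classify_sources conserves totals and supports weights", {
  hits <- data.frame(source = c(rep("chromosome", 91), rep("plasmid", 9)))
  got <- classify_sources(hits)
  expect_identical(unname(got), c(91, 9, 0, 0))
  expect_identical(unname(classify_sources(hits[0, , drop = FALSE])),
                   c(0, 0, 0, 0))
  w <- rep(2, 100)
  expect_identical(sum(classify_sources(hits, w)), 200)
})

test_that("every planted error-free event is recovered exactly end to end", {
  cfg <- quick_sim(seed = 40, n_events = 120, parental = 0, pi = 0.4, w = 10)
  sim <- simulate_run(cfg)
  parsed <- parse_reads(sim$reads, sim$refgen$model)
  tal <- collapse_duplicates(parsed$spacers$spacer)
  hits <- map_spacers(tal$tally$spacer, sim$refgen$refs)
  m <- merge(hits, sim$events, by = "spacer",
             suffixes = c(".got", ".true"))
  expect_identical(nrow(m), nrow(tal$tally))
  expect_true(all(m$source.got == m$source.true))
  expect_true(all(m$start.got == m$start.true))
  expect_true(all(m$strand.got == m$strand.true))
  expect_true(all(m$pam.got == m$pam.true))
  expect_true(all(m$edit_distance == 0L))
})
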