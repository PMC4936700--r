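test_that("generators are deterministic under a fixed seed", {
  d <- small_design(seed = 7)
  r1 <- build_reference(d)
  r2 <- build_reference(d)
  expect_identical(r1, r2)
  t1 <- simulate_srna_libraries(r1$reference, r1$truth, d, r1$class_map)
  t2 <- simulate_srna_libraries(r2$reference, r2$truth, d, r2$class_map)
  expect_identical(t1, t2)
  g1 <- simulate_degradome(r1$reference, r1$truth, d)
  g2 <- simulate_degradome(r1$reference, r1$truth, d)
  expect_identical(g1, g2)
})

test_that("infeasible designs are rejected up front", {
  expect_error(synthetic_design(depth = 0), "depth")
  expect_error(synthetic_design(transcript_length = c(40L, 100L)),
               "cannot host")
  expect_error(synthetic_design(n_transcripts = 5L, n_mirnas = 10L),
               "2 transcripts per")
  expect_error(synthetic_design(class_fractions = c(miRNA = 0.5, rRNA = 0.2,
                                                    tRNA = 0.1, snRNA = 0.05,
                                                    snoRNA = 0.05,
                                                    unann = 0.2)),
               "sum to 1")
})

test_that("planted precursors satisfy the screening geometry and energy", {
  d <- small_design(seed = 42)
  rt <- build_reference(d)
  m <- rt$truth$mirnas
  for (i in seq_len(nrow(m))) {
    tx <- rt$reference$seq[match(m$transcript[i], rt$reference$id)]
    pre <- substr(tx, m$pre_start[i] + 1, m$pre_end[i])
    expect_equal(substr(pre, 1, 21), m$mature[i])
    expect_equal(substr(pre, nchar(pre) - 20, nchar(pre)), m$star[i])
    f <- fold(pre)
    expect_lte(f$mfe, -18)
    expect_true(duplex_check(f$structure, c(0L, 21L)))
  }
  # planted targets carry perfect-complement sites at recorded coordinates
  tg <- rt$truth$targets
  for (i in seq_len(nrow(tg))) {
    expect_equal(tg$cleavage_pos[i], tg$site_start[i] + 21L - 10L)
  }
})

test_that("zero dispersion gives Poisson library totals near depth", {
  d <- small_design(seed = 15, dispersion = 0)
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  libs <- tag_libraries(tab)
  # control libraries have expected total = depth (treated ones shift with
  # the planted fold changes); allow 3 sigma plus class-weight granularity
  for (lib in c("PA2", "PA4")) {
    expect_lt(abs(sum(tab[[lib]]) - d$depth), 3 * sqrt(d$depth) + 0.02 * d$depth)
  }
})

test_that("true fold changes propagate into the planted counts", {
  d <- synthetic_design(n_transcripts = 12L, n_mirnas = 6L,
                        transcript_length = c(300L, 500L), depth = 2e5,
                        true_log2fc = c(2, -2, 0, 0, 2, 0),
                        dispersion = 0, seed = 33)
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  m <- rt$truth$mirnas
  cnt <- tab[match(m$mature, tab$tag), ]
  emp_lfc <- log2((cnt$PA2H + 0.5) / (cnt$PA2 + 0.5))
  expect_equal(emp_lfc, m$true_log2fc, tolerance = 0.35)
})

test_that("null designs show no systematic fold change", {
  lfcs <- c()
  for (seed in 1:10) {
    d <- synthetic_design(n_transcripts = 10L, n_mirnas = 5L,
                          transcript_length = c(300L, 500L), depth = 1e5,
                          true_log2fc = 0, seed = seed)
    rt <- build_reference(d)
    tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
    m <- rt$truth$mirnas
    cnt <- tab[match(m$mature, tab$tag), ]
    lfcs <- c(lfcs, log2((cnt$PA2H + 0.5) / (cnt$PA2 + 0.5)))
  }
  expect_lt(median(abs(lfcs)), 0.2)
})

test_that("class composition converges to the design fractions", {
  d <- synthetic_design(true_log2fc = 0, seed = 27)  # depth 1e6, defaults
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  m <- rt$truth$mirnas
  is_mir <- tab$tag %in% c(m$mature, m$star)
  total <- sum(tab$PA2)
  mir_frac <- sum(tab$PA2[is_mir]) / total
  expect_lt(abs(mir_frac - d$class_fractions[["miRNA"]]), 0.01)
  cls <- annotate_tags(tab[!is_mir, ], rt$class_map)
  for (cl in c("rRNA", "tRNA")) {
    frac <- sum(cls$PA2[cls$class == cl]) / total
    expect_lt(abs(frac - d$class_fractions[[cl]]), 0.01)
  }
})

test_that("degradome simulation plants dominant peaks and honors rate 0", {
  d <- small_design(seed = 21, deg_background_rate = 0)
  rt <- build_reference(d)
  deg <- simulate_degradome(rt$reference, rt$truth, d)
  profs <- build_profiles(deg, rt$reference)
  tg <- rt$truth$targets
  planted_tx <- unique(tg$transcript)
  for (txid in names(profs)) {
    nz <- which(profs[[txid]]$counts > 0) - 1L
    if (txid %in% planted_tx) {
      expect_setequal(nz, tg$cleavage_pos[tg$transcript == txid])
    } else {
      expect_length(nz, 0)
    }
  }

  # with background, the planted site is still the transcript-wide maximum
  d2 <- small_design(seed = 22)  # peak 50, rate 1
  rt2 <- build_reference(d2)
  deg2 <- simulate_degradome(rt2$reference, rt2$truth, d2)
  profs2 <- build_profiles(deg2, rt2$reference)
  tg2 <- rt2$truth$targets
  at_max <- vapply(seq_len(nrow(tg2)), function(i) {
    pr <- profs2[[tg2$transcript[i]]]
    pr$counts[tg2$cleavage_pos[i] + 1L] == pr$max
  }, logical(1))
  expect_gte(mean(at_max), 0.8)
})

test_that("FASTQ expansion appends the adapter and fixes read length", {
  d <- small_design(seed = 2, depth = 500)
  tt <- tag_table(c("ACGTACGTACGTACGTACGTA", "GGCCGGTTAACCGGTTAACC"),
                  matrix(c(2L, 1L, 0L, 3L, 1L, 1L, 2L, 0L), 2, 4,
                         dimnames = list(NULL, d$libraries)))
  dir <- withr::local_tempdir()
  write_synthetic_fastq(tt, d, dir)
  rd <- read_fastq(file.path(dir, "PA2.fastq"))
  expect_equal(nrow(rd), 3L)
  expect_true(all(nchar(rd$seq) == d$read_len))
  # cleaning the synthetic reads recovers the tags
  cl <- clean_reads(rd, adapter3 = d$adapter3)
  expect_setequal(unique(cl$reads), tt$tag[tt$PA2 > 0])
})

test_that("truth tables round-trip to TSV", {
  d <- small_design(seed = 3)
  rt <- build_reference(d)
  dir <- withr::local_tempdir()
  write_truth(rt$truth, dir)
  back <- read.delim(file.path(dir, "mirnas.tsv"))
  expect_equal(back$mature, rt$truth$mirnas$mature)
  expect_equal(readLines(file.path(dir, "seed.txt")), "3")
})
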