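test_that("bundled fold matches the brute-force enumeration on small RNAs", {
  # a perfect mini-hairpin
  f <- fold("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)
  expect_equal(f$mfe, bf_mfe("GGGGAAAACCCC"))

  # unpairable input stays open with zero energy
  f <- fold("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$mfe, 0)

  set.seed(12)
  for (rep in 1:30) {
    s <- random_dna(sample(6:18, 1))
    f <- fold(s)
    expect_equal(f$mfe, min(0, bf_mfe(s)), info = s)
  }
})

test_that("fold output is balanced, same length, and energy-consistent", {
  set.seed(21)
  for (rep in 1:20) {
    s <- random_dna(sample(30:120, 1), gc = runif(1, 0.3, 0.7))
    f <- fold(s)
    expect_equal(nchar(f$structure), nchar(s))
    p <- pairing_table(f$structure)  # errors if unbalanced
    paired <- which(!is.na(p))
    expect_equal(p[p[paired]], paired)  # pairing is an involution
    expect_lte(f$mfe, 0)
  }
})

test_that("sequences with too many Ns are reported unfoldable, not errors", {
  f <- fold("NNNNNNACGTACGTACGT")
  expect_false(f$ok)
  expect_match(f$reason, "N fraction")
})

test_that("the vienna backend parses RNAfold output", {
  s <- paste0(strrep("G", 10), strrep("A", 6), strrep("C", 10))
  f <- fold(s, backend = "vienna")
  expect_equal(f$backend, "vienna")
  expect_equal(nchar(f$structure), nchar(s))
  expect_lt(f$mfe, -10)
  expect_silent(pairing_table(f$structure))
})

test_that("hairpin metrics follow their definitions", {
  m <- hairpin_metrics(strrep("GCAT", 25), -50)  # len 100, gc 0.5
  expect_equal(m$amfe, -50)
  expect_equal(m$mfei, -1)
  expect_equal(m$gc, 0.5)
  expect_equal(hairpin_metrics("ACGT", 0)$amfe, 0)
  expect_equal(hairpin_metrics("ACGT", 0)$mfei, 0)
  expect_true(is.na(hairpin_metrics("ATAT", -1)$mfei))
})

test_that("candidate windows follow the flank arithmetic and clustering", {
  ref <- data.frame(id = "t1", seq = random_dna(500), stringsAsFactors = FALSE)
  aln <- data.frame(tag = "x", transcript = "t1", start = 100L, end = 121L,
                    count = 10)
  win <- extract_candidates(aln, ref)
  expect_equal(sort(win$win_start), c(0L, 80L))
  expect_equal(sort(win$win_end), c(141L, 321L))

  # a tag at the transcript start clips at 0
  aln$start <- 0L; aln$end <- 21L
  win <- extract_candidates(aln, ref)
  expect_true(all(win$win_start == 0L))

  # two tags 2 nt apart form one cluster
  aln2 <- data.frame(tag = c("x", "y"), transcript = "t1",
                     start = c(100L, 123L), end = c(121L, 144L),
                     count = c(5, 5))
  win <- extract_candidates(aln2, ref)
  expect_equal(unique(win$cluster_start), 100L)
  expect_equal(unique(win$cluster_end), 144L)
})

test_that("duplex geometry accepts planted precursors and rejects violations", {
  d <- small_design(seed = 2)
  rt <- build_reference(d)
  m <- rt$truth$mirnas
  for (i in seq_len(nrow(m))) {
    tx <- rt$reference$seq[match(m$transcript[i], rt$reference$id)]
    pre <- substr(tx, m$pre_start[i] + 1, m$pre_end[i])
    f <- fold(pre)
    expect_lte(f$mfe, -18)
    expect_equal(n_hairpin_loops(f$structure), 1L)
    expect_true(duplex_check(f$structure, c(0L, 21L)))
    expect_true(duplex_check(f$structure, c(0L, 21L),
                             star_span = c(m$star_start[i] - m$pre_start[i],
                                           m$star_end[i] - m$pre_start[i])))
  }

  # mature placed across the terminal loop pairs with itself -> reject
  pre <- substr(rt$reference$seq[match(m$transcript[1], rt$reference$id)],
                m$pre_start[1] + 1, m$pre_end[1])
  f <- fold(pre)
  expect_false(duplex_check(f$structure, c(10L, 40L)))

  # a blunt-ended duplex (star = full reverse complement, no 3' overhang)
  mat <- "GCGGCGATCGATTGCCGGCAT"
  blunt <- paste0(mat, "ACACACACACAC",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(mat))))
  fb <- fold(blunt)
  expect_false(duplex_check(fb$structure, c(0L, 21L),
                            star_span = c(33L, 54L)))
})

test_that("processing precision counts reads near mature/star 5' ends", {
  expect_equal(processing_precision(rep(0L, 10), rep(1, 10), c(0L, 21L)), 1)
  expect_equal(processing_precision(c(0L, rep(9L, 19)), c(1, rep(1, 19)),
                                    c(0L, 21L)), 0.05)
  expect_true(is.na(processing_precision(integer(0), numeric(0), c(0L, 21L))))
  # star 5' ends count toward the numerator
  expect_equal(processing_precision(c(0L, 33L), c(5, 5), c(0L, 21L),
                                    star_span = c(33L, 54L)), 1)
})

test_that("screen_novel applies the four criteria and the precision filter", {
  d <- small_design(seed = 6)
  rt <- build_reference(d)
  m <- rt$truth$mirnas[1, ]
  ref <- rt$reference[rt$reference$id == m$transcript, ]
  mk_aln <- function(count) data.frame(
    tag = m$mature, transcript = m$transcript,
    start = m$mature_start, end = m$mature_end, count = count,
    stringsAsFactors = FALSE)
  win <- extract_candidates(mk_aln(50), ref)

  sc <- screen_novel(win, mk_aln(50), ref)
  expect_true(any(sc$accepted))
  acc <- sc[sc$accepted, ][1, ]
  expect_lte(acc$mfe, -18)
  expect_equal(acc$precision, 1)
  # stored metrics recompute from stored fields
  expect_equal(acc$amfe, acc$mfe / (acc$pre_end - acc$pre_start) * 100)
  expect_equal(acc$mfei, acc$amfe / (acc$gc * 100))

  # four reads fall below the abundance criterion
  sc4 <- screen_novel(win, mk_aln(4), ref)
  expect_false(any(sc4$accepted))
  expect_true("count<5" %in% sc4$reason)

  # low processing precision removes the candidate: bury the mature (which
  # still clears the count criterion) among scattered degradation 5' ends
  # on the same precursor
  offs <- 3L + (1:60 %% 25L)
  noisy <- rbind(mk_aln(6),
                 data.frame(tag = paste0("bg", 1:60),
                            transcript = m$transcript,
                            start = m$pre_start + offs,
                            end = m$pre_start + offs + 21L,
                            count = 1, stringsAsFactors = FALSE))
  scp <- screen_novel(win, noisy, ref)
  expect_false(any(scp$accepted))
  expect_true("precision" %in% scp$reason)
})

test_that("screen_novel is monotone in min_reads and precision_min", {
  d <- small_design(seed = 13)
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  ann <- annotate_tags(tab, rt$class_map)
  un <- ann[ann$class == "unann", setdiff(names(ann), c("class", "catalog_id",
                                                        "catalog_mm"))]
  aln <- align_tags(un, rt$reference)
  win <- extract_candidates(aln, rt$reference)
  base <- screen_novel(win, aln, rt$reference)
  stricter <- screen_novel(win, aln, rt$reference, min_reads = 50,
                           precision_min = 0.5)
  key <- function(df) paste(df$transcript, df$pre_start, df$pre_end)
  expect_true(all(key(stricter[stricter$accepted, ]) %in%
                    key(base[base$accepted, ])))
})

test_that("shuffled precursors rarely pass the structural criteria", {
  d <- small_design(seed = 19)
  rt <- build_reference(d)
  m <- rt$truth$mirnas[1, ]
  pre <- substr(rt$reference$seq[match(m$transcript, rt$reference$id)],
                m$pre_start + 1, m$pre_end)
  set.seed(99)
  passes <- 0L
  for (i in 1:100) {
    s <- dinucleotide_shuffle(pre)
    f <- fold(s)
    ok <- isTRUE(f$ok) && n_hairpin_loops(f$structure) == 1L &&
      duplex_check(f$structure, c(0L, 21L)) && f$mfe <= -18
    passes <- passes + ok
  }
  expect_lte(passes, 10L)
})
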