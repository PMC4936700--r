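ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("clean_reads enforces the 18-30 nt insert window", {
  mk <- function(len) paste0(random_dna(len, gc = 0.6), ADAPTER)
  set.seed(5)
  r17 <- clean_reads(mk(17), adapter3 = ADAPTER)
  expect_equal(r17$stats$removed$too_short, 1L)
  expect_equal(r17$stats$clean, 0L)

  r30 <- clean_reads(mk(30), adapter3 = ADAPTER)
  expect_equal(r30$stats$clean, 1L)
  expect_equal(nchar(r30$reads), 30L)

  r31 <- clean_reads(mk(31), adapter3 = ADAPTER)
  expect_equal(r31$stats$removed$too_long, 1L)
})

test_that("poly-A, low-quality and adapter-less reads are removed in order", {
  polyA <- strrep("A", 20)
  res <- clean_reads(polyA, adapter3 = NULL)
  expect_equal(res$stats$removed$poly_a, 1L)

  # quality is assessed before everything else
  reads <- data.frame(seq = polyA, qual = strrep("!", 20))
  res <- clean_reads(reads, adapter3 = NULL, min_q = 20)
  expect_equal(res$stats$removed$low_quality, 1L)
  expect_equal(res$stats$removed$poly_a, 0L)

  # a read with no recognizable 3' adapter is dropped as adapter-missing
  res <- clean_reads("GTCGTCGTCGTCGTCGTCGTCGTCGTCC", adapter3 = "AAAATTTT")
  expect_equal(res$stats$removed$no_adapter, 1L)
})

test_that("adapter trimming finds the longest adapter prefix at the 3' end", {
  insert <- "GTCCAGTTACGATCTGCAGT"  # 20 nt
  res <- clean_reads(paste0(insert, ADAPTER), adapter3 = ADAPTER)
  expect_equal(res$reads, insert)
  # one mismatch in >= 10 matched adapter bases is tolerated
  adap_mm <- paste0("TGGAATTCTCGG", "T", substr(ADAPTER, 14, 21))
  res <- clean_reads(paste0(insert, adap_mm), adapter3 = ADAPTER)
  expect_equal(res$reads, insert)
})

test_that("cleaning conserves reads: raw = clean + sum(removed)", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    reads <- vapply(sample(10:40, n, replace = TRUE), function(l)
      paste0(random_dna(l), substr(ADAPTER, 1, sample(0:21, 1))),
      character(1))
    st <- clean_reads(reads, adapter3 = ADAPTER)$stats
    expect_equal(st$raw, st$clean + sum(unlist(st$removed)))
    expect_lte(st$unique, st$clean)
  }
})

test_that("collapse counts distinct sequences per library", {
  tt <- collapse_reads(list(L1 = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                                   "GGGATTTACCGTGCAATC")))
  expect_equal(tt$L1[match("ACGTACGTACGTACGTAC", tt$tag)], 2L)
  expect_equal(tt$L1[match("GGGATTTACCGTGCAATC", tt$tag)], 1L)

  # identical multisets in two libraries give identical columns
  r <- c("ACGTACGTACGTACGTAC", "GGGATTTACCGTGCAATC", "ACGTACGTACGTACGTAC")
  tt <- collapse_reads(list(A = r, B = r))
  expect_equal(tt$A, tt$B)

  # conservation on random input
  set.seed(8)
  reads <- vapply(rep(21, 200), random_dna, character(1))
  reads <- sample(reads, 500, replace = TRUE)
  tt <- collapse_reads(list(X = reads))
  expect_equal(sum(tt$X), 500L)
})

test_that("length distributions sum to totals and find the 24-nt mode", {
  tt <- tag_table("ACGTACGTACGTACGTACGTA", matrix(5L, 1, 1,
                                                  dimnames = list(NULL, "L")))
  expect_equal(unname(length_distribution(tt, weighted = TRUE)["21", "L"]), 5L)
  expect_equal(unname(length_distribution(tt, weighted = FALSE)["21", "L"]), 1L)

  empty <- tag_table(character(0), matrix(integer(), 0, 1,
                                          dimnames = list(NULL, "L")))
  expect_true(all(length_distribution(empty) == 0L))

  # the synthetic background emulates the 24-nt-dominant length profile
  d <- small_design(seed = 4)
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  bg <- tab[!(tab$tag %in% c(rt$truth$mirnas$mature, rt$truth$mirnas$star)), ]
  ld <- length_distribution(bg, weighted = TRUE)
  expect_equal(rownames(ld)[which.max(rowSums(ld))], "24")
})

test_that("match_conserved applies the two-mismatch cap with end shifts", {
  catalog <- data.frame(id = c("miR1", "miR2"),
                        seq = c("TGGAGAAGCAGGGCACGTGCA",
                                "TTGGACTGAAGGGAGCTCCCT"),
                        stringsAsFactors = FALSE)
  expect_equal(match_conserved("TGGAGAAGCAGGGCACGTGCA", catalog)$mismatches, 0L)
  two <- "TGGACAAGCAGGGCACGTGCT"  # 2 substitutions vs miR1
  hit <- match_conserved(two, catalog)
  expect_equal(hit$id, "miR1")
  expect_equal(hit$mismatches, 2L)
  three <- "TGGACAAGCAGGCCACGTGCT"  # 3 substitutions
  expect_null(match_conserved(three, catalog))
  # a 2-nt 5' truncation still matches through the end-shift scan
  trunc <- substr(catalog$seq[2], 3, 21)
  expect_equal(match_conserved(trunc, catalog)$id, "miR2")
})

test_that("annotation assigns exactly one class with rRNA priority", {
  rseq <- "TCCCTGGTGGTCTAGTGGTTAGGATTCGGCGCTCTCACCGCCGCGGCCCGGGTTCGATTCCCGG"
  catalog <- data.frame(id = "miR9", seq = substr(rseq, 10, 30),
                        stringsAsFactors = FALSE)
  tt <- tag_table(c(substr(rseq, 10, 30), "GATCGGCCTAAGGCTTACGAT"),
                  matrix(c(3L, 1L), 2, 1, dimnames = list(NULL, "L")))
  ann <- annotate_tags(tt, class_map = list(rRNA = rseq), catalog = catalog)
  # tag matches both an rRNA fragment and the catalog: rRNA wins
  expect_equal(ann$class, c("rRNA", "unann"))
  expect_true(is.na(ann$catalog_id[1]))

  summ <- annotation_summary(ann)
  pct <- summ$L_unique_pct[summ$category != "Total"]
  expect_equal(sum(pct), 100, tolerance = 0.02)
})

test_that("planted background tags recover their class on synthetic data", {
  d <- small_design(seed = 9)
  rt <- build_reference(d)
  tab <- simulate_srna_libraries(rt$reference, rt$truth, d, rt$class_map)
  ann <- annotate_tags(tab, rt$class_map, catalog = NULL)
  # every ncRNA-class tag is a substring of its class reference, so recovery
  # should be essentially perfect (a fragment may collide with a higher-
  # priority class by chance)
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    in_class <- vapply(ann$tag, function(tg)
      any(grepl(tg, rt$class_map[[cl]], fixed = TRUE)), logical(1))
    expect_gte(mean(ann$class[in_class] == cl), 0.99)
  }
  expect_true(all(ann$class %in% c("miRNA", "rRNA", "snRNA", "snoRNA",
                                   "tRNA", "unann")))
})
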