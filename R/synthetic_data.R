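# Synthetic four-library study generator: planted hairpin precursors,
# class-annotated background tags, differential miRNA abundances and
# degradome cleavage peaks, together with a machine-readable truth object.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_seq <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Vectorized: one random sequence per element of `lens`.
random_seqs <- function(lens, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(length(lens))
  for (l in unique(lens)) {
    idx <- which(lens == l)
    mat <- matrix(sample(names(p), length(idx) * l, replace = TRUE, prob = p),
                  nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  out
}

# Negative binomial with variance mu + dispersion * mu^2;
# dispersion 0 degenerates to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Describe a synthetic four-library study design
#'
#' The defaults emulate the drought study layout this package models: four
#' libraries (PA2 and PA4 controls, PA2H and PA4H drought-stressed), planted
#' 21-nt miRNAs on hairpin precursors hosted by reference transcripts,
#' background tags from annotated ncRNA classes and from transcript
#' degradation, a 24-nt-dominant background length distribution, and one
#' planted degradome cleavage peak per miRNA opposite its positions 10-11.
#'
#' @param n_transcripts Number of reference transcripts; must be at least
#'   `2 * n_mirnas` (one host and one target transcript per planted miRNA).
#' @param transcript_length Length range (min, max) in nt.
#' @param gc GC fraction of random sequence.
#' @param n_mirnas Number of planted miRNAs.
#' @param mature_len,loop_len Mature and terminal-loop lengths in nt.
#' @param libraries Library names; the second and fourth are the stressed
#'   counterparts of the first and third.
#' @param depth Sequencing depth (reads) per library.
#' @param true_log2fc Per-miRNA true log2 fold change (stressed over
#'   control, applied to both genotype pairs); recycled to `n_mirnas`.
#' @param dispersion Negative-binomial dispersion d (variance `mu + d mu^2`);
#'   0 gives Poisson counts.
#' @param class_fractions Named fractions of library depth per annotation
#'   class (miRNA, rRNA, tRNA, snRNA, snoRNA, unann); must sum to 1.
#' @param star_fraction Star read abundance as a fraction of mature.
#' @param background_tag_mean Named numeric vector: mean reads per unique
#'   background tag, per class. The number of unique tags per class is the
#'   class depth divided by this mean, which reproduces the unique/total
#'   ratios typical of real sRNA libraries (degradation tags are mostly
#'   near-singletons, tRNA fragments are few but abundant).
#' @param unann_mapped_fraction Fraction of unann tags drawn as transcript
#'   degradation fragments (the rest are unmappable random tags).
#' @param base_rpm Range of baseline miRNA abundances (RPM), sampled
#'   log-uniformly then scaled so the miRNA class fraction is met.
#' @param deg_peak_height Expected degradome reads at a planted cleavage
#'   site, per library.
#' @param deg_background_rate Expected degradome background reads per
#'   transcript position, per library.
#' @param deg_tag_len Degradome tag length (nt).
#' @param adapter3 3' adapter used by the FASTQ writer.
#' @param read_len Instrument read length for the FASTQ writer.
#' @param seed Integer seed recorded in the truth object; all generators
#'   derive their RNG stream from it.
#' @return A validated list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_transcripts = 50L,
                             transcript_length = c(400L, 1200L),
                             gc = 0.45,
                             n_mirnas = 20L,
                             mature_len = 21L,
                             loop_len = 12L,
                             libraries = c("PA2", "PA2H", "PA4", "PA4H"),
                             depth = 1e6,
                             true_log2fc = c(2, -2, 0, 0),
                             dispersion = 0.01,
                             class_fractions = c(miRNA = 0.20, rRNA = 0.05,
                                                 tRNA = 0.05, snRNA = 0.002,
                                                 snoRNA = 0.001, unann = 0.697),
                             star_fraction = 0.1,
                             background_tag_mean = c(rRNA = 10, tRNA = 50,
                                                     snRNA = 2.5, snoRNA = 2.5,
                                                     unann = 3),
                             unann_mapped_fraction = 0.5,
                             base_rpm = c(50, 2000),
                             deg_peak_height = 50,
                             deg_background_rate = 1,
                             deg_tag_len = 20L,
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             read_len = 36L,
                             seed = 1L) {
  d <- list(n_transcripts = as.integer(n_transcripts),
            transcript_length = as.integer(transcript_length), gc = gc,
            n_mirnas = as.integer(n_mirnas),
            mature_len = as.integer(mature_len),
            loop_len = as.integer(loop_len), libraries = libraries,
            depth = depth,
            true_log2fc = rep_len(true_log2fc, n_mirnas),
            dispersion = dispersion, class_fractions = class_fractions,
            star_fraction = star_fraction,
            background_tag_mean = background_tag_mean,
            unann_mapped_fraction = unann_mapped_fraction,
            base_rpm = base_rpm, deg_peak_height = deg_peak_height,
            deg_background_rate = deg_background_rate,
            deg_tag_len = as.integer(deg_tag_len), adapter3 = adapter3,
            read_len = as.integer(read_len), seed = as.integer(seed))
  if (d$depth <= 0) stop("library depth must be positive", call. = FALSE)
  if (any(d$class_fractions < 0) || any(d$class_fractions > 1) ||
      abs(sum(d$class_fractions) - 1) > 1e-8)
    stop("class fractions must lie in [0,1] and sum to 1", call. = FALSE)
  if (d$gc <= 0 || d$gc >= 1) stop("gc must lie in (0,1)", call. = FALSE)
  if (d$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  pre_len <- 2L * d$mature_len + d$loop_len
  if (d$transcript_length[1L] < max(60L, pre_len))
    stop(sprintf("transcripts (min %d nt) cannot host a %d-nt precursor",
                 d$transcript_length[1L], pre_len), call. = FALSE)
  if (d$n_transcripts < 2L * d$n_mirnas)
    stop("need at least 2 transcripts per planted miRNA (host + target)",
         call. = FALSE)
  if (length(d$libraries) != 4L)
    stop("the design uses exactly four libraries", call. = FALSE)
  class(d) <- "synthetic_design"
  d
}

# Draw a mature sequence whose planted duplex is guaranteed to clear the
# MFE acceptance threshold under the bundled energy model: the designed
# 19-bp helix scores (3 hairpin + 2 helix-opening) - sum over its 18 stacks
# (2 per GC outer pair, 1 otherwise) = -13 - #GC, so >= 8 G/C among the
# first 18 bases gives <= -21 kcal/mol.
draw_mature <- function(len, gc) {
  repeat {
    m <- random_seq(len, gc)
    head18 <- substr(m, 1L, 18L)
    if (nchar(gsub("[^GC]", "", head18)) >= 8L) return(m)
  }
}

#' Build the synthetic reference and ground truth
#'
#' Generates reference transcripts, plants one hairpin precursor per miRNA
#' (mature + loop + star, where the star is the reverse complement of the
#' mature's first 19 nt plus a 2-nt 3' tail, giving the canonical 2-nt
#' 3'-overhang duplex), plants one perfectly complementary target site per
#' miRNA on a separate transcript, and generates ncRNA class reference
#' sequences. All randomness derives from `design$seed`.
#'
#' @param design A [synthetic_design()].
#' @return A list with `reference` (record data frame), `class_map` (named
#'   list of class sequences) and `truth` (list with `mirnas`, `targets`
#'   data frames, per-library true RPM, and the seed).
#' @export
build_reference <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    n_tx <- design$n_transcripts
    lens <- sample(design$transcript_length[1L]:design$transcript_length[2L],
                   n_tx, replace = TRUE)
    tx <- vapply(lens, random_seq, character(1L), gc = design$gc)
    ids <- sprintf("TX%04d", seq_len(n_tx))

    nm <- design$n_mirnas
    mature <- vapply(rep(design$mature_len, nm), draw_mature, character(1L),
                     gc = 0.5)
    # Loop bases come from {A,C} (which cannot pair with each other); the
    # two loop bases at the helix junction are chosen so they cannot pair
    # with the mature's 2-nt 3' overhang, otherwise the MFE fold would
    # extend the helix into the loop and break the planted 2-nt-overhang
    # duplex geometry.
    loop <- vapply(seq_len(nm), function(i) {
      l <- sample(c("A", "C"), design$loop_len, replace = TRUE)
      tail_m <- substr(mature[i], design$mature_len - 1L, design$mature_len)
      m19 <- substr(tail_m, 1L, 1L)
      m20 <- substr(tail_m, 2L, 2L)
      l[design$loop_len] <- if (m19 == "T") "C" else "A"
      l[design$loop_len - 1L] <- if (m20 == "T") "C" else "A"
      paste(l, collapse = "")
    }, character(1L))
    tail2 <- vapply(seq_len(nm), function(i)
      paste(sample(c("A", "C"), 2L, replace = TRUE), collapse = ""),
      character(1L))
    star <- paste0(revcomp(substr(mature, 1L, design$mature_len - 2L)), tail2)
    precursor <- paste0(mature, loop, star)
    pre_len <- nchar(precursor)

    host <- seq_len(nm)
    target <- nm + seq_len(nm)
    pre_start <- integer(nm)
    for (i in seq_len(nm)) {
      max_off <- nchar(tx[host[i]]) - pre_len[i]
      off <- sample.int(max_off + 1L, 1L) - 1L
      substr(tx[host[i]], off + 1L, off + pre_len[i]) <- precursor[i]
      pre_start[i] <- off
    }
    L <- design$mature_len
    site_seq <- revcomp(mature)
    site_start <- integer(nm)
    for (i in seq_len(nm)) {
      max_off <- nchar(tx[target[i]]) - L - 2L
      off <- sample.int(max_off + 1L, 1L) - 1L
      substr(tx[target[i]], off + 1L, off + L) <- site_seq[i]
      # the target site contains the reverse complement of the mature, whose
      # 3' part equals the star's first 19 nt; pin the two following bases
      # to G/T (the star tail is drawn from {A,C}) so the star tag cannot
      # coincidentally align full-length across the site
      substr(tx[target[i]], off + L + 1L, off + L + 2L) <- "GT"
      site_start[i] <- off
    }

    class_map <- list(
      rRNA = vapply(rep(300L, 5L), random_seq, character(1L), gc = design$gc),
      tRNA = vapply(rep(75L, 10L), random_seq, character(1L), gc = design$gc),
      snRNA = vapply(rep(150L, 5L), random_seq, character(1L), gc = design$gc),
      snoRNA = vapply(rep(120L, 5L), random_seq, character(1L), gc = design$gc))

    base <- exp(runif(nm, log(design$base_rpm[1L]), log(design$base_rpm[2L])))
    mirna_frac <- design$class_fractions[["miRNA"]]
    # mature + star reads together make up the miRNA class fraction
    base <- base * (mirna_frac * 1e6) /
      (sum(base) * (1 + design$star_fraction))
    lfc <- design$true_log2fc
    rpm <- cbind(base, base * 2^lfc, base, base * 2^lfc)
    colnames(rpm) <- design$libraries

    mirnas <- data.frame(
      id = sprintf("syn-miR%03d", seq_len(nm)),
      mature = mature, star = star, transcript = ids[host],
      pre_start = pre_start, pre_end = pre_start + pre_len,
      mature_start = pre_start, mature_end = pre_start + L,
      star_start = pre_start + L + design$loop_len,
      star_end = pre_start + pre_len,
      true_log2fc = lfc, stringsAsFactors = FALSE)
    mirnas <- cbind(mirnas, as.data.frame(rpm))
    targets <- data.frame(
      mirna = mirnas$id, transcript = ids[target],
      site_start = site_start, site_end = site_start + L,
      cleavage_pos = site_start + L - 10L, stringsAsFactors = FALSE)

    list(reference = data.frame(id = ids, desc = "", seq = tx,
                                stringsAsFactors = FALSE),
         class_map = class_map,
         truth = list(mirnas = mirnas, targets = targets,
                      libraries = design$libraries, seed = design$seed))
  })
}

# sRNA-like tag length distribution over 18..30 nt: 24-nt dominant, then 21.
SRNA_LENGTHS <- 18:30
SRNA_LENGTH_WEIGHTS <- c(2, 2, 3, 12, 4, 3, 30, 6, 4, 3, 2, 2, 2)

# Sample background tag sequences for one class: substrings of the given
# source sequences with the sRNA-like length distribution, avoiding masked
# intervals (per source, 0-based half-open, 5-nt guard band).
sample_fragments <- function(sources, n, masks = NULL) {
  out <- character(0)
  rounds <- 0L
  slen <- nchar(sources)
  while (length(out) < n && rounds < 50L) {
    rounds <- rounds + 1L
    todo <- n - length(out)
    k <- sample.int(length(sources), todo, replace = TRUE)
    l <- sample(SRNA_LENGTHS, todo, replace = TRUE,
                prob = SRNA_LENGTH_WEIGHTS)
    ok <- slen[k] >= l
    k <- k[ok]; l <- l[ok]
    if (length(k) == 0L) next
    s <- floor(runif(length(k)) * (slen[k] - l + 1L))
    if (!is.null(masks)) {
      bad <- vapply(seq_along(k), function(r) {
        m <- masks[[k[r]]]
        !is.null(m) && any(s[r] < m[, 2L] + 5L & s[r] + l[r] > m[, 1L] - 5L)
      }, logical(1L))
      k <- k[!bad]; l <- l[!bad]; s <- s[!bad]
    }
    if (length(k)) out <- c(out, substr(sources[k], s + 1L, s + l))
  }
  out
}

#' Simulate the four sRNA libraries as a tag table
#'
#' Planted mature and star tags receive negative-binomial counts with mean
#' `true RPM x depth / 1e6` (dispersion from the design; 0 gives Poisson).
#' Background tags are drawn per class: ncRNA tags are substrings of the
#' class reference sequences, `unann` tags are a mix of transcript
#' degradation fragments (masked away from planted precursors) and
#' unmappable random tags. Per-tag abundances follow a gamma-weighted
#' power-law-like profile, scaled to the class depth fractions.
#'
#' @param reference,truth From [build_reference()].
#' @param design The same [synthetic_design()].
#' @param class_map Class sequences from [build_reference()].
#' @return A `tag_table` with one count column per library.
#' @export
simulate_srna_libraries <- function(reference, truth, design,
                                    class_map = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (design$depth <= 0) stop("library depth must be positive", call. = FALSE)
  with_seed(design$seed + 1L, {
    libs <- design$libraries
    depth <- design$depth
    mir <- truth$mirnas
    tags <- c(mir$mature, mir$star)
    mu <- rbind(as.matrix(mir[libs]), as.matrix(mir[libs]) * design$star_fraction)
    mu <- mu * depth / 1e6

    fr <- design$class_fractions
    tag_mean <- design$background_tag_mean
    masks <- lapply(reference$id, function(id) {
      rows <- mir$transcript == id
      if (any(rows)) cbind(mir$pre_start[rows], mir$pre_end[rows]) else NULL
    })
    for (cl in names(tag_mean)) {
      if (fr[[cl]] == 0) next
      n_cl <- max(1L, round(fr[[cl]] * depth / tag_mean[[cl]]))
      if (cl == "unann") {
        n_map <- round(n_cl * design$unann_mapped_fraction)
        frag <- sample_fragments(reference$seq, n_map, masks)
        rnd <- random_seqs(sample(SRNA_LENGTHS, n_cl - n_map, replace = TRUE,
                                  prob = SRNA_LENGTH_WEIGHTS),
                           gc = design$gc)
        cl_tags <- c(frag, rnd)
      } else {
        cl_tags <- sample_fragments(class_map[[cl]], n_cl)
      }
      wts <- rgamma(length(cl_tags), shape = 0.7)
      wts <- wts / sum(wts)
      cl_mu <- matrix(rep(wts * fr[[cl]] * depth, length(libs)),
                      ncol = length(libs), dimnames = list(NULL, libs))
      tags <- c(tags, cl_tags)
      mu <- rbind(mu, cl_mu)
    }

    counts <- matrix(0L, length(tags), length(libs),
                     dimnames = list(NULL, libs))
    for (j in seq_along(libs)) {
      counts[, j] <- rcounts(length(tags), mu[, j], design$dispersion)
    }
    # aggregate duplicate tag sequences (fragment collisions)
    agg <- rowsum(counts, group = tags)
    tag_table(rownames(agg), agg, libs)
  })
}

#' Simulate degradome tag libraries
#'
#' Every planted cleavage site receives a Poisson count peak of
#' `deg_peak_height` fixed-length tags whose 5' ends start exactly at the
#' cleavage position (the transcript base paired to miRNA position 10);
#' a uniform Poisson background of `deg_background_rate` expected reads per
#' transcript position is added on top (0 disables it).
#'
#' @param reference,truth From [build_reference()].
#' @param design The same [synthetic_design()].
#' @return A `tag_table` of degradome tags with one column per library.
#' @export
simulate_degradome <- function(reference, truth, design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed + 2L, {
    libs <- design$libraries
    tlen <- design$deg_tag_len
    tx_seq <- setNames(reference$seq, reference$id)
    tags <- character(0)
    counts <- NULL
    for (i in seq_len(nrow(truth$targets))) {
      t0 <- truth$targets[i, ]
      s <- tx_seq[[t0$transcript]]
      if (t0$cleavage_pos + tlen > nchar(s)) next
      tags <- c(tags, substr(s, t0$cleavage_pos + 1L, t0$cleavage_pos + tlen))
      counts <- rbind(counts, rpois(length(libs), design$deg_peak_height))
    }
    if (design$deg_background_rate > 0) {
      bg_tag <- character(0)
      bg_lib <- character(0)
      for (r in seq_along(tx_seq)) {
        s <- tx_seq[[r]]
        npos <- nchar(s) - tlen + 1L
        if (npos < 1L) next
        nbg <- rpois(1L, design$deg_background_rate * npos)
        if (nbg == 0L) next
        pos <- sample.int(npos, nbg, replace = TRUE)
        bg_tag <- c(bg_tag, substring(s, pos, pos + tlen - 1L))
        bg_lib <- c(bg_lib, sample(libs, nbg, replace = TRUE))
      }
      if (length(bg_tag)) {
        bg <- table(factor(bg_tag), factor(bg_lib, levels = libs))
        bg_counts <- matrix(as.integer(bg), nrow(bg), length(libs))
        tags <- c(tags, rownames(bg))
        counts <- rbind(counts, bg_counts)
      }
    }
    if (length(tags) == 0L) {
      return(tag_table(character(0),
                       matrix(integer(), 0L, length(libs),
                              dimnames = list(NULL, libs)), libs))
    }
    colnames(counts) <- libs
    agg <- rowsum(counts, group = tags)
    tag_table(rownames(agg), agg, libs)
  })
}

#' Expand a simulated tag table into adapter-ligated FASTQ reads
#'
#' Each tag is emitted `count` times with the 3' adapter appended, padded
#' with `A` or truncated to the instrument read length, with constant
#' quality `I` (Phred 40). Intended for small designs exercising the
#' cleaning stage.
#'
#' @param table A `tag_table`.
#' @param design A [synthetic_design()] (adapter and read length).
#' @param dir Output directory; one `<library>.fastq` per library.
#' @return Invisibly, the written file paths.
#' @export
write_synthetic_fastq <- function(table, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- tag_libraries(table)
  paths <- character(0)
  for (lib in libs) {
    cnt <- table[[lib]]
    idx <- rep(seq_len(nrow(table)), cnt)
    seqs <- paste0(table$tag[idx], design$adapter3)
    seqs <- ifelse(nchar(seqs) >= design$read_len,
                   substr(seqs, 1L, design$read_len),
                   paste0(seqs, strrep("A", design$read_len - nchar(seqs))))
    reads <- data.frame(
      id = sprintf("%s_%06d", lib, seq_along(idx)),
      seq = seqs, qual = strrep("I", design$read_len),
      stringsAsFactors = FALSE)
    path <- file.path(dir, paste0(lib, ".fastq"))
    write_fastq(reads, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the synthetic truth tables as TSV
#'
#' @param truth Truth object from [build_reference()].
#' @param dir Output directory (`mirnas.tsv`, `targets.tsv`,
#'   `seed.txt`).
#' @return Invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$mirnas, file.path(dir, "mirnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$targets, file.path(dir, "targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(as.character(truth$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
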