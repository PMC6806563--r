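#' Construct an amplicon quantification container
#'
#' Holds per-region read tallies from targeted deep sequencing of one
#' amplicon: total and mapped read counts, reads carrying an indel
#' overlapping the region, and per-position base counts among mapped reads.
#'
#' @param reference_sequence amplicon reference (plus strand).
#' @param total_reads,mapped_reads,indel_reads integer tallies with
#'   `indel_reads <= mapped_reads <= total_reads`.
#' @param base_counts matrix with rows A,C,G,T and one column per reference
#'   position (counts among mapped reads).
#' @param region label, e.g. "amplicon:1-120".
#' @return An `amplicon_quant`.
#' @export
amplicon_quant <- function(reference_sequence, total_reads, mapped_reads,
                           indel_reads, base_counts, region = "amplicon") {
  reference_sequence <- toupper(reference_sequence)
  total_reads <- as.integer(total_reads)
  mapped_reads <- as.integer(mapped_reads)
  indel_reads <- as.integer(indel_reads)
  if (!(indel_reads <= mapped_reads && mapped_reads <= total_reads))
    stop("need indel_reads <= mapped_reads <= total_reads", call. = FALSE)
  if (!is.matrix(base_counts) ||
      !identical(rownames(base_counts), c("A", "C", "G", "T")))
    stop("base_counts must be a matrix with rows A,C,G,T", call. = FALSE)
  if (ncol(base_counts) != nchar(reference_sequence))
    stop("base_counts has ", ncol(base_counts), " columns but reference is ",
         nchar(reference_sequence), " nt", call. = FALSE)
  if (any(colSums(base_counts) > mapped_reads))
    stop("per-position counts exceed mapped_reads", call. = FALSE)
  structure(list(region = region, total_reads = total_reads,
                 mapped_reads = mapped_reads, indel_reads = indel_reads,
                 base_counts = base_counts,
                 reference_sequence = reference_sequence),
            class = "amplicon_quant")
}

#' @export
print.amplicon_quant <- function(x, ...) {
  cat(sprintf("<amplicon_quant> %s: %d total / %d mapped / %d indel reads, %d nt reference\n",
              x$region, x$total_reads, x$mapped_reads, x$indel_reads,
              nchar(x$reference_sequence)))
  invisible(x)
}

#' Indel frequency of an amplicon
#'
#' Reads containing at least one inserted and/or deleted nucleotide divided
#' by all mapped reads over the region.
#'
#' @param q an `amplicon_quant`.
#' @return Fraction in \[0, 1\].
#' @export
indel_frequency <- function(q) {
  stopifnot(inherits(q, "amplicon_quant"))
  if (q$mapped_reads == 0L)
    stop("indel frequency undefined: no mapped reads", call. = FALSE)
  q$indel_reads / q$mapped_reads
}

#' Base substitution frequency at one position
#'
#' Reads carrying `to_base` at `position` divided by total reads (the
#' denominator is total, not mapped, reads; set `denominator = "mapped"` to
#' switch).
#'
#' @param q an `amplicon_quant`.
#' @param position 1-based position in the amplicon reference.
#' @param from_base expected reference base at `position` (checked).
#' @param to_base substituted base counted.
#' @param denominator "total" (default) or "mapped".
#' @return Fraction in \[0, 1\].
#' @export
substitution_frequency <- function(q, position, from_base, to_base,
                                   denominator = c("total", "mapped")) {
  stopifnot(inherits(q, "amplicon_quant"))
  denominator <- match.arg(denominator)
  position <- as.integer(position)
  refb <- substr(q$reference_sequence, position, position)
  if (refb != toupper(from_base))
    stop("reference base at position ", position, " is '", refb,
         "', not '", from_base, "'", call. = FALSE)
  den <- if (denominator == "total") q$total_reads else q$mapped_reads
  if (den == 0L) stop("no reads", call. = FALSE)
  unname(q$base_counts[toupper(to_base), position]) / den
}

#' Product purity at a target cytosine
#'
#' Among edited (non-reference) reads at a reference-C position, the
#' fraction carrying the intended C-to-T outcome rather than C-to-A or
#' C-to-G. Returns `NA` (an explicit undefined marker, never silently 0)
#' when no read is edited. Set `mode = "of_all_reads"` for the alternative
#' C-to-T-among-all-reads reading.
#'
#' @param q an `amplicon_quant`.
#' @param position 1-based reference-C position (target-strand view).
#' @param mode "of_edited" (default) or "of_all_reads".
#' @return Fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
product_purity <- function(q, position, mode = c("of_edited",
                                                 "of_all_reads")) {
  stopifnot(inherits(q, "amplicon_quant"))
  mode <- match.arg(mode)
  position <- as.integer(position)
  refb <- substr(q$reference_sequence, position, position)
  if (refb != "C")
    stop("product purity requires a reference C at position ", position,
         " (found '", refb, "')", call. = FALSE)
  ct <- unname(q$base_counts["T", position])
  edited <- ct + unname(q$base_counts["A", position]) +
    unname(q$base_counts["G", position])
  if (mode == "of_all_reads") {
    if (q$total_reads == 0L) stop("no reads", call. = FALSE)
    return(ct / q$total_reads)
  }
  if (edited == 0L) return(NA_real_)
  ct / edited
}

#' Normalize per-editor values to a reference editor
#'
#' Each editor's value divided by the reference editor's value, times 100
#' (the reference editor reads 100%).
#'
#' @param freqs named numeric vector of per-editor values.
#' @param reference_editor name of the editor set to 100%.
#' @return Named numeric vector of percentages.
#' @examples
#' normalize_to_reference(c(BE3 = 0.20, X = 0.40), "BE3")
#' @export
normalize_to_reference <- function(freqs, reference_editor = "BE3") {
  if (!reference_editor %in% names(freqs))
    stop("reference editor '", reference_editor, "' not present",
         call. = FALSE)
  ref <- freqs[[reference_editor]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference editor value must be > 0", call. = FALSE)
  100 * freqs / ref
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Computes the one-tailed Mann-Whitney/Wilcoxon rank-sum p-value: exact by
#' enumeration of the rank-sum null distribution when the combined sample
#' size is at most 20 and there are no ties, and by normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative "greater" (a tends larger than b) or "less".
#' @return p-value.
#' @examples
#' rank_sum_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")  # exact 1/20
#' @export
rank_sum_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of sample a
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 + n2 <= 20L) {
    # exact: count arrangements by enumerating all choose(n1+n2, n1)
    # assignments of ranks to sample a
    combos <- utils::combn(n1 + n2, n1)
    u_null <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- if (alternative == "greater") mean(u_null >= U) else
      mean(u_null <= U)
    return(p)
  }
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
  if (sigma2 <= 0) return(1)
  z <- switch(alternative,
              greater = (U - mu - 0.5) / sqrt(sigma2),
              less = (U - mu + 0.5) / sqrt(sigma2))
  if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z)
}

#' Build an amplicon_quant from SAM alignments
#'
#' Converts the SAM to BAM, tallies per-position base counts with a pileup
#' over mapped reads, and counts a read as containing an indel iff its
#' alignment has at least one insertion or deletion operation overlapping
#' the region. Secondary and supplementary alignments are ignored.
#'
#' @param sam_path path to a SAM file aligned to the amplicon reference.
#' @param reference_sequence the amplicon reference sequence (plus strand).
#' @param contig contig name used in the SAM (default: first in header).
#' @param region 1-based inclusive `c(start, end)` interval defining "the
#'   region" for indel overlap; defaults to the whole reference.
#' @param min_mapq MAPQ threshold for the mapped-read tallies.
#' @return An `amplicon_quant`.
#' @export
quantify_sam <- function(sam_path, reference_sequence, contig = NULL,
                         region = NULL, min_mapq = 0L) {
  reference_sequence <- toupper(reference_sequence)
  reflen <- nchar(reference_sequence)
  if (is.null(region)) region <- c(1L, reflen)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    flag = flag0, what = c("qname", "flag", "rname", "pos", "cigar",
                           "mapq")))[[1]]
  total <- length(aln$flag)
  is_mapped <- !bitwAnd(aln$flag, 4L) & !is.na(aln$pos) &
    (is.na(aln$mapq) | aln$mapq >= min_mapq)
  if (is.null(contig)) {
    lv <- levels(aln$rname)
    contig <- if (length(lv)) lv[1] else "amplicon"
  }
  is_mapped <- is_mapped & as.character(aln$rname) == contig
  mapped <- sum(is_mapped)

  # indel reads: any I/D cigar op whose reference footprint overlaps region
  indel <- 0L
  if (mapped > 0) {
    cig <- aln$cigar[is_mapped]
    pos <- aln$pos[is_mapped]
    has_id <- grepl("[ID]", cig)
    if (any(has_id)) {
      rngs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig[has_id], pos = pos[has_id], ops = c("I", "D"))
      hit <- vapply(seq_along(rngs), function(i) {
        r <- rngs[[i]]
        if (!length(r)) return(FALSE)
        # an insertion has width 0 on the reference; treat its anchor point
        st <- IRanges::start(r); en <- pmax(IRanges::end(r), st)
        any(st <= region[2] & en >= region[1])
      }, logical(1))
      indel <- sum(hit)
    }
  }

  counts <- matrix(0L, nrow = 4, ncol = reflen,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (mapped > 0) {
    pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                                 distinguish_nucleotides = TRUE,
                                 min_base_quality = 0L, min_mapq = min_mapq,
                                 max_depth = 10000000L,
                                 min_nucleotide_depth = 1L,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    sbp <- Rsamtools::ScanBamParam(
      flag = flag0,
      which = GenomicRanges::GRanges(contig, IRanges::IRanges(1L, reflen)))
    pile <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
    pile <- pile[pile$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
    for (i in seq_len(nrow(pile)))
      counts[as.character(pile$nucleotide[i]), pile$pos[i]] <-
        counts[as.character(pile$nucleotide[i]), pile$pos[i]] +
        pile$count[i]
  }
  amplicon_quant(reference_sequence, total, mapped, indel, counts,
                 region = paste0(contig, ":", region[1], "-", region[2]))
}

#' Build an amplicon_quant from a simplified pileup TSV
#'
#' The pileup dialect is a tab-separated table with columns `pos`, `ref`,
#' `A`, `C`, `G`, `T` (per-position counts among mapped reads), preceded by
#' header comments `#total_reads=`, `#mapped_reads=`, `#indel_reads=`.
#'
#' @param path pileup TSV path.
#' @return An `amplicon_quant`.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("pileup header missing #", key, "=", call. = FALSE)
    as.integer(sub(paste0("^#", key, "="), "", m[1]))
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("pos", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(tab)))
    stop("pileup must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[order(tab$pos), , drop = FALSE]
  counts <- t(as.matrix(tab[, c("A", "C", "G", "T")]))
  rownames(counts) <- c("A", "C", "G", "T")
  storage.mode(counts) <- "integer"
  amplicon_quant(paste(tab$ref, collapse = ""), getv("total_reads"),
                 getv("mapped_reads"), getv("indel_reads"), counts)
}

#' Write the simplified pileup TSV for an amplicon_quant
#'
#' @param q an `amplicon_quant`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(q, path) {
  stopifnot(inherits(q, "amplicon_quant"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#total_reads=", q$total_reads),
               paste0("#mapped_reads=", q$mapped_reads),
               paste0("#indel_reads=", q$indel_reads)), con)
  tab <- data.frame(pos = seq_len(ncol(q$base_counts)),
                    ref = strsplit(q$reference_sequence, "")[[1]],
                    A = q$base_counts["A", ], C = q$base_counts["C", ],
                    G = q$base_counts["G", ], T = q$base_counts["T", ])
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
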