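# Synthetic inputs with recorded ground truth. The brute-force enumerator
# here is deliberately naive and shares no code with enumerate_guides(): it
# slides EVERY possible protospacer placement and checks window membership
# and PAM match independently, so it can serve as the oracle in tests.

#' Naive brute-force guide enumeration (oracle)
#'
#' Independent reference enumerator: tries every protospacer start position
#' on the target strand, keeps placements whose window covers the target C
#' and whose PAM matches, rejecting any placement touching a non-ACGT base.
#' Used to validate [enumerate_guides()]; intentionally slow and simple.
#'
#' @inheritParams enumerate_guides
#' @return data.frame with the same columns as [enumerate_guides()],
#'   ordered by window position.
#' @export
brute_force_guides <- function(target, editor) {
  stopifnot(inherits(target, "flanked_target"),
            inherits(editor, "editor_spec"))
  n <- nchar(target$sequence)
  if (target$target_strand == "+") {
    s <- target$sequence
    t0 <- target$target_offset
  } else {
    s <- revcomp(target$sequence)
    t0 <- n - 1L - target$target_offset
  }
  L <- editor$spacer_length
  plen <- nchar(editor$pam_pattern)
  iupac_ok <- function(code, base) base %in% IUPAC_SETS[[code]]
  rows <- list()
  for (a in 0:(n - L)) {                     # every protospacer placement
    p <- t0 - a + 1L                         # window position of target C
    if (p < editor$window_start || p > editor$window_end) next
    if (editor$pam_side == "three_prime") {
      pam_from <- a + L
    } else {
      pam_from <- a - plen
    }
    if (pam_from < 0L || pam_from + plen > n) next
    proto <- substr(s, a + 1L, a + L)
    pam <- substr(s, pam_from + 1L, pam_from + plen)
    if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) next
    ok <- TRUE
    for (k in seq_len(plen))
      if (!iupac_ok(substr(editor$pam_pattern, k, k), substr(pam, k, k))) {
        ok <- FALSE; break
      }
    if (!ok) next
    bys <- integer(0)
    for (q in editor$window_start:editor$window_end) {
      if (q == p) next
      if (substr(s, a + q, a + q) == "C") bys <- c(bys, q)
    }
    ps <- if (target$target_strand == "+") a else n - (a + L)
    rows[[length(rows) + 1L]] <- data.frame(
      editor = editor$name, strand = target$target_strand,
      protospacer_start = ps, protospacer_end = ps + L,
      spacer_seq = proto, pam_seq = pam, window_pos = p,
      bystanders = paste(bys, collapse = ","),
      n_bystanders = length(bys), preferential = length(bys) == 0L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_guide_frame()
  out <- out[order(out$window_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc_fraction = 0.5) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a reproducible random genome FASTA
#'
#' @param n_contigs number of contigs.
#' @param length contig length in nt (>= 200).
#' @param gc_fraction target GC content in \[0, 1\].
#' @param seed RNG seed; the same seed reproduces identical bytes.
#' @param path output FASTA path (default: a tempfile).
#' @return The FASTA path, with attributes `contigs` (names) and
#'   `base_composition` (overall A/C/G/T counts).
#' @export
generate_genome <- function(n_contigs = 1L, length = 10000L,
                            gc_fraction = 0.5, seed = 1L, path = NULL) {
  if (length < 200L) stop("contig length must be >= 200", call. = FALSE)
  if (is.null(path)) path <- tempfile(fileext = ".fa")
  set.seed(seed)
  seqs <- vapply(seq_len(n_contigs), function(i)
    random_dna(length, gc_fraction), character(1))
  names(seqs) <- paste0("contig", seq_len(n_contigs))
  con <- file(path, "wb")     # binary mode: byte-identical across platforms
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), con, sep = "\n")
  close(con)
  comp <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                       levels = c("A", "C", "G", "T")))
  attr(path, "contigs") <- names(seqs)
  attr(path, "base_composition") <- as.integer(comp)
  names(attr(path, "base_composition")) <- c("A", "C", "G", "T")
  path
}

#' Plant SNVs with oracle-computed ground truth
#'
#' Places `n_variants` SNVs at random eligible sites of the genome according
#' to `class_mix`, then runs the naive [brute_force_guides()] enumerator
#' (never the production path) for every panel editor to record the true
#' targetable / preferential flags.
#'
#' Class `create_c_to_t` picks reference C or G sites (the SNV to install);
#' class `correct_t_to_c` picks reference T or A sites whose pathogenic
#' allele is the corresponding C or G.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param n_variants number of SNVs to plant.
#' @param class_mix named fractions for `create_c_to_t` and
#'   `correct_t_to_c` (must sum to 1).
#' @param panel `editor_panel` used for the ground truth.
#' @param seed RNG seed.
#' @param flank flank half-width used by the oracle.
#' @return List with `variants` (list of `variant_record`s) and
#'   `ground_truth` (data.frame: variant_id, editor, targetable,
#'   preferential — one row per variant x editor).
#' @export
plant_variants <- function(genome, n_variants, class_mix =
                             c(create_c_to_t = 0.5, correct_t_to_c = 0.5),
                           panel = load_panel(), seed = 1L, flank = 30L) {
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(inherits(genome, "DNAStringSet"))
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1", call. = FALSE)
  set.seed(seed)
  flank <- check_flank(flank, panel)
  n_create <- round(n_variants * class_mix[["create_c_to_t"]])
  n_correct <- n_variants - n_create
  chroms <- names(genome)
  pick_sites <- function(bases, n_pick) {
    pool <- do.call(rbind, lapply(chroms, function(ch) {
      sq <- as.character(genome[[ch]])
      idx <- which(strsplit(sq, "")[[1]] %in% bases)
      idx <- idx[idx > flank & idx <= nchar(sq) - flank]
      if (!length(idx)) return(NULL)
      data.frame(chrom = ch, pos = idx, base = substring(sq, idx, idx),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pool) || nrow(pool) < n_pick)
      stop("not enough eligible ", paste(bases, collapse = "/"),
           " sites for ", n_pick, " variants", call. = FALSE)
    pool[sample(nrow(pool), n_pick), , drop = FALSE]
  }
  variants <- list()
  if (n_create > 0) {
    sites <- pick_sites(c("C", "G"), n_create)
    for (i in seq_len(nrow(sites))) {
      refb <- sites$base[i]
      altb <- if (refb == "C") "T" else "A"
      id <- sprintf("SYN_CR%04d", i)
      variants[[length(variants) + 1L]] <- variant_record(
        sites$chrom[i], sites$pos[i], refb, altb, variant_id = id,
        name = sprintf("SYN(%s):c.%d%s>%s", id, sites$pos[i], refb, altb))
    }
  }
  if (n_correct > 0) {
    sites <- pick_sites(c("T", "A"), n_correct)
    for (i in seq_len(nrow(sites))) {
      refb <- sites$base[i]
      altb <- if (refb == "T") "C" else "G"
      id <- sprintf("SYN_CO%04d", i)
      variants[[length(variants) + 1L]] <- variant_record(
        sites$chrom[i], sites$pos[i], refb, altb, variant_id = id,
        name = sprintf("SYN(%s):c.%d%s>%s", id, sites$pos[i], refb, altb))
    }
  }
  gt <- list()
  for (v in variants) {
    cls <- classify_edit(v)
    tgt <- extract_flank(genome, v, cls, flank = flank)
    for (e in panel$editors) {
      g <- brute_force_guides(tgt, e)
      gt[[length(gt) + 1L]] <- data.frame(
        variant_id = v$variant_id, editor = e$name,
        targetable = nrow(g) > 0L,
        preferential = nrow(g) > 0L && any(g$preferential),
        stringsAsFactors = FALSE)
    }
  }
  list(variants = variants,
       ground_truth = do.call(rbind, c(gt, make.row.names = FALSE)))
}

#' Write variants as a ClinVar-style table
#'
#' @param variants list of `variant_record`s.
#' @param path output TSV path.
#' @param assembly assembly label written for every row.
#' @return `path`, invisibly.
#' @export
write_clinvar_table <- function(variants, path, assembly = "GRCh38") {
  tab <- do.call(rbind, lapply(variants, function(v) data.frame(
    Type = "single nucleotide variant", Name = v$name,
    ClinicalSignificance = "Pathogenic", Assembly = assembly,
    Chromosome = v$chrom, Start = v$pos, ReferenceAllele = v$ref_allele,
    AlternateAllele = v$alt_allele, VariationID = v$variant_id,
    GeneSymbol = v$gene_symbol, PhenotypeIDS = v$phenotype,
    stringsAsFactors = FALSE)))
  con <- file(path, "wb")
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Generate a ClinVar-like table of known composition
#'
#' Builds a synthetic variant_summary-style table mixing pathogenic SNVs of
#' both edit classes with distractor rows (other significance labels, indel
#' types, other assemblies) and records the planted composition for exact
#' recovery tests.
#'
#' @param n_rows total rows.
#' @param seed RNG seed.
#' @param path optional output TSV; when `NULL` the data.frame is returned.
#' @return List with `table` (data.frame or path) and `truth` (named counts:
#'   pathogenic_snv_grch38, create_c_to_t, correct_t_to_c, other_snv).
#' @export
generate_clinvar_fixture <- function(n_rows = 1000L, seed = 1L,
                                     path = NULL) {
  set.seed(seed)
  kinds <- sample(c("keep_ct", "keep_tc", "keep_other", "likely", "indel",
                    "grch37"), n_rows, replace = TRUE,
                  prob = c(0.25, 0.2, 0.05, 0.2, 0.15, 0.15))
  base_pairs <- list(keep_ct = c("C", "T"), keep_tc = c("T", "C"),
                     keep_other = c("A", "T"))
  rows <- lapply(seq_len(n_rows), function(i) {
    kind <- kinds[i]
    pos <- 1000L + i                       # unique → survives deduplication
    pair <- base_pairs[[kind]]
    if (is.null(pair)) pair <- c("C", "T")
    nm <- sprintf("NM_%06d.1(GENE%d):c.%d%s>%s", i, i %% 50L, pos,
                  pair[1], pair[2])
    data.frame(
      Type = if (kind == "indel") "Deletion" else
        "single nucleotide variant",
      Name = nm,
      ClinicalSignificance = switch(kind, likely = "Likely pathogenic",
                                    "Pathogenic"),
      Assembly = if (kind == "grch37") "GRCh37" else "GRCh38",
      Chromosome = "1", Start = pos,
      ReferenceAllele = pair[1], AlternateAllele = pair[2],
      VariationID = sprintf("VCV%07d", i), GeneSymbol =
        sprintf("GENE%d", i %% 50L),
      PhenotypeIDS = sprintf("MONDO:%07d", i %% 100L),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  truth <- c(pathogenic_snv_grch38 =
               sum(kinds %in% c("keep_ct", "keep_tc", "keep_other")),
             create_c_to_t = sum(kinds == "keep_ct"),
             correct_t_to_c = sum(kinds == "keep_tc"),
             other_snv = sum(kinds == "keep_other"))
  if (!is.null(path)) {
    con <- file(path, "wb")
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(list(table = path, truth = truth))
  }
  list(table = tab, truth = truth)
}

#' Simulate amplicon reads with planted editing and indel rates
#'
#' Each read independently: with probability `indel_rate` it carries a 1-bp
#' insertion or deletion at the edit position (so the indel overlaps the
#' editing window); otherwise, with probability `editing_rate`, the target C
#' becomes T with probability `purity` or A/G (equal split) with the
#' remainder. Reads span the whole reference and are written as SAM.
#'
#' @param reference amplicon reference sequence.
#' @param edit_position 1-based position of the target C in `reference`.
#' @param editing_rate,purity,indel_rate rates in \[0, 1\].
#' @param n_reads number of reads.
#' @param seed RNG seed; identical seeds give identical files.
#' @param path output SAM path (default tempfile).
#' @param contig contig name written in the header.
#' @return The SAM path, with attribute `planted` (the parameters) and
#'   `tallies` (true simulated counts: n_indel, n_edited, n_t, n_a, n_g).
#' @export
simulate_reads <- function(reference, edit_position, editing_rate = 0.3,
                           purity = 0.9, indel_rate = 0.05,
                           n_reads = 10000L, seed = 1L, path = NULL,
                           contig = "amplicon") {
  reference <- toupper(reference)
  reflen <- nchar(reference)
  stopifnot(edit_position >= 1L, edit_position <= reflen)
  for (r in c(editing_rate, purity, indel_rate))
    if (r < 0 || r > 1) stop("rates must be in [0,1]", call. = FALSE)
  if (substr(reference, edit_position, edit_position) != "C")
    stop("reference base at edit_position must be C", call. = FALSE)
  if (is.null(path)) path <- tempfile(fileext = ".sam")
  set.seed(seed)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", contig, "\tLN:", reflen))
  body <- character(n_reads)
  n_indel <- 0L; n_edited <- 0L
  n_t <- 0L; n_a <- 0L; n_g <- 0L
  for (i in seq_len(n_reads)) {
    qname <- sprintf("read%06d", i)
    if (stats::runif(1) < indel_rate) {
      n_indel <- n_indel + 1L
      if (stats::runif(1) < 0.5) {
        # 1-bp deletion of the edit position
        seq <- paste0(substr(reference, 1, edit_position - 1L),
                      substr(reference, edit_position + 1L, reflen))
        cigar <- sprintf("%dM1D%dM", edit_position - 1L,
                         reflen - edit_position)
      } else {
        # 1-bp insertion immediately after the edit position
        seq <- paste0(substr(reference, 1, edit_position), "A",
                      substr(reference, edit_position + 1L, reflen))
        cigar <- sprintf("%dM1I%dM", edit_position,
                         reflen - edit_position)
      }
    } else {
      seq <- reference
      cigar <- sprintf("%dM", reflen)
      if (stats::runif(1) < editing_rate) {
        n_edited <- n_edited + 1L
        newb <- if (stats::runif(1) < purity) "T" else
          sample(c("A", "G"), 1L)
        if (newb == "T") n_t <- n_t + 1L
        else if (newb == "A") n_a <- n_a + 1L
        else n_g <- n_g + 1L
        substr(seq, edit_position, edit_position) <- newb
      }
    }
    body[i] <- paste(qname, 0L, contig, 1L, 60L, cigar, "*", 0L, 0L,
                     seq, strrep("I", nchar(seq)), sep = "\t")
  }
  con <- file(path, "wb")
  writeLines(c(header, body), con, sep = "\n")
  close(con)
  attr(path, "planted") <- list(editing_rate = editing_rate,
                                purity = purity, indel_rate = indel_rate,
                                n_reads = n_reads, seed = seed,
                                edit_position = edit_position)
  attr(path, "tallies") <- c(n_indel = n_indel, n_edited = n_edited,
                             n_t = n_t, n_a = n_a, n_g = n_g)
  path
}

#' Build a fixture manifest
#'
#' Bundles the paths and parameters of a generated fixture set so a run can
#' be replayed exactly from its seed.
#'
#' @param seed master seed.
#' @param genome FASTA path.
#' @param variants variant table path.
#' @param ground_truth ground-truth data.frame from [plant_variants()].
#' @param params list of simulation parameters.
#' @return A `fixture_manifest`.
#' @export
fixture_manifest <- function(seed, genome = NULL, variants = NULL,
                             ground_truth = NULL, params = list()) {
  structure(list(seed = as.integer(seed), genome = genome,
                 variants = variants, ground_truth = ground_truth,
                 params = params),
            class = "fixture_manifest")
}
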