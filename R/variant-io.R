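#' Construct a single-nucleotide variant record
#'
#' @param chrom contig name.
#' @param pos 1-based genomic coordinate of the SNV.
#' @param ref_allele,alt_allele single unambiguous bases, ref != alt.
#' @param variant_id identifier (ClinVar VariationID, dbSNP rs, ...).
#' @param name HGVS-like variant name (used for edit classification).
#' @param significance,phenotype,gene_symbol,assembly annotations.
#' @return A `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref_allele, alt_allele,
                           variant_id = NA_character_, name = "",
                           significance = "", phenotype = "",
                           gene_symbol = "", assembly = "") {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L)
    stop("'pos' must be a positive 1-based coordinate", call. = FALSE)
  for (al in c(ref_allele, alt_allele))
    if (!al %in% c("A", "C", "G", "T"))
      stop("SNV alleles must be single unambiguous bases, got '", al, "'",
           call. = FALSE)
  if (ref_allele == alt_allele)
    stop("ref and alt alleles are identical ('", ref_allele, "')",
         call. = FALSE)
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 variant_id = as.character(variant_id),
                 name = as.character(name),
                 significance = as.character(significance),
                 phenotype = as.character(phenotype),
                 gene_symbol = as.character(gene_symbol),
                 assembly = as.character(assembly)),
            class = "variant_record")
}

default_clinvar_columns <- function() {
  c(type = "Type", significance = "ClinicalSignificance", name = "Name",
    assembly = "Assembly", chrom = "Chromosome", pos = "Start",
    ref = "ReferenceAllele", alt = "AlternateAllele",
    variant_id = "VariationID", gene_symbol = "GeneSymbol",
    phenotype = "PhenotypeIDS")
}

#' Filter a ClinVar-style variant table down to pathogenic SNVs
#'
#' Applies the filtering pipeline: keep rows typed as single nucleotide
#' variants, with clinical significance exactly "Pathogenic"
#' (case-insensitive exact label by default; compound labels such as
#' "Pathogenic/Likely pathogenic" are excluded unless listed in
#' `significance_labels`), on the requested assembly, then deduplicates by
#' (chrom, pos, ref, alt). Rows with unparsable coordinates or non-SNV
#' alleles are skipped and counted.
#'
#' @param records data.frame in ClinVar `variant_summary` dialect, or a path
#'   to such a tab-separated file.
#' @param columns named character vector mapping the logical fields
#'   (`type`, `significance`, `name`, `assembly`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_id`, `gene_symbol`, `phenotype`) to column names.
#' @param assembly genome assembly label to keep (default "GRCh38").
#' @param significance_labels significance labels accepted (exact,
#'   case-insensitive).
#' @param deduplicate drop rows duplicating an earlier (chrom,pos,ref,alt).
#' @return List of `variant_record`s, with attribute `filter_counts` giving
#'   the row count surviving each step (input, snv, pathogenic, assembly,
#'   parsable, deduplicated) and `n_skipped` for unparsable rows.
#' @export
filter_clinvar <- function(records, columns = default_clinvar_columns(),
                           assembly = "GRCh38",
                           significance_labels = "pathogenic",
                           deduplicate = TRUE) {
  if (is.character(records) && length(records) == 1L)
    records <- utils::read.table(records, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE, quote = "",
                                 comment.char = "", check.names = FALSE)
  miss <- setdiff(unname(columns[c("type", "significance", "name",
                                   "assembly", "chrom", "pos")]),
                  names(records))
  if (length(miss))
    stop("input table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  counts <- c(input = nrow(records))
  grab <- function(df, key) {
    col <- columns[[key]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else
      rep("", nrow(df))
  }

  keep <- tolower(trimws(grab(records, "type"))) %in%
    c("single nucleotide variant", "snv")
  records <- records[keep, , drop = FALSE]
  counts["snv"] <- nrow(records)

  keep <- tolower(trimws(grab(records, "significance"))) %in%
    tolower(significance_labels)
  records <- records[keep, , drop = FALSE]
  counts["pathogenic"] <- nrow(records)

  keep <- trimws(grab(records, "assembly")) == assembly
  records <- records[keep, , drop = FALSE]
  counts["assembly"] <- nrow(records)

  pos <- suppressWarnings(as.integer(grab(records, "pos")))
  ref <- toupper(trimws(grab(records, "ref")))
  alt <- toupper(trimws(grab(records, "alt")))
  ok <- !is.na(pos) & pos >= 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(n_skipped, " row(s) skipped: unparsable coordinate or non-SNV ",
            "alleles", call. = FALSE)
  records <- records[ok, , drop = FALSE]
  pos <- pos[ok]; ref <- ref[ok]; alt <- alt[ok]
  counts["parsable"] <- nrow(records)

  chrom <- as.character(grab(records, "chrom"))
  if (deduplicate) {
    keep <- !duplicated(paste(chrom, pos, ref, alt, sep = ":"))
    records <- records[keep, , drop = FALSE]
    pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    chrom <- chrom[keep]
  }
  counts["deduplicated"] <- nrow(records)

  out <- lapply(seq_len(nrow(records)), function(i)
    variant_record(chrom[i], pos[i], ref[i], alt[i],
                   variant_id = as.character(grab(records, "variant_id")[i]),
                   name = as.character(grab(records, "name")[i]),
                   significance = as.character(grab(records,
                                                    "significance")[i]),
                   phenotype = as.character(grab(records, "phenotype")[i]),
                   gene_symbol = as.character(grab(records,
                                                   "gene_symbol")[i]),
                   assembly = assembly))
  attr(out, "filter_counts") <- counts
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classify a variant as a create or correct target
#'
#' Uses the variant-name substring rule: names containing "C>T" or "G>A"
#' are C-to-T/G-to-A SNVs that a cytosine base editor can *create*
#' (install); names containing "T>C" or "A>G" are T-to-C/A-to-G SNVs it can
#' *correct* (revert). A name matching both is ambiguous and returns
#' `"not_applicable"` with a warning. When the name carries neither pattern
#' (e.g. plain VCF input), the ref/alt alleles are used with the same
#' mapping.
#'
#' @param record a `variant_record`.
#' @return One of `"create_c_to_t"`, `"correct_t_to_c"`,
#'   `"not_applicable"`.
#' @examples
#' classify_edit(variant_record("1", 100, "T", "C",
#'                              name = "NM_000061.3(BTK):c.1588T>C"))
#' @export
classify_edit <- function(record) {
  nm <- record$name
  has_ct <- nzchar(nm) && grepl("C>T|G>A", nm, fixed = FALSE)
  has_tc <- nzchar(nm) && grepl("T>C|A>G", nm, fixed = FALSE)
  if (has_ct && has_tc) {
    warning("variant name '", nm, "' matches both C-to-T and T-to-C ",
            "patterns; classified not_applicable", call. = FALSE)
    return("not_applicable")
  }
  if (has_ct) return("create_c_to_t")
  if (has_tc) return("correct_t_to_c")
  if (nzchar(nm)) return("not_applicable")
  # allele fallback for name-less input
  key <- paste0(record$ref_allele, ">", record$alt_allele)
  switch(key,
         "C>T" = , "G>A" = "create_c_to_t",
         "T>C" = , "A>G" = "correct_t_to_c",
         "not_applicable")
}

#' Construct a flanked target directly from a sequence
#'
#' Low-level constructor used by [scan_sequence()] and the fixture
#' generator; [extract_flank()] is the genome-aware entry point.
#'
#' @param sequence plus-strand nucleotide string.
#' @param target_offset 0-based index of the editable base in `sequence`.
#' @param target_strand "+" if that base reads C on the plus strand, "-" if
#'   it is a G (a C on the minus strand).
#' @param edited_sequence_applied whether an alt allele was substituted in.
#' @return A `flanked_target`.
#' @export
flanked_target <- function(sequence, target_offset, target_strand,
                           edited_sequence_applied = FALSE) {
  sequence <- toupper(sequence)
  target_offset <- as.integer(target_offset)
  if (target_offset < 0L || target_offset >= nchar(sequence))
    stop("target_offset out of range", call. = FALSE)
  if (!target_strand %in% c("+", "-"))
    stop("target_strand must be '+' or '-'", call. = FALSE)
  base <- substr(sequence, target_offset + 1L, target_offset + 1L)
  want <- if (target_strand == "+") "C" else "G"
  if (base != want)
    stop("base at target_offset is '", base, "' but strand ", target_strand,
         " requires '", want, "'", call. = FALSE)
  structure(list(sequence = sequence, target_offset = target_offset,
                 target_strand = target_strand,
                 edited_sequence_applied = edited_sequence_applied),
            class = "flanked_target")
}

genome_fetch <- function(genome, chrom, start, end) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Rsamtools::FaFile(ensure_fai(genome))
  if (inherits(genome, "FaFile")) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    return(as.character(Rsamtools::scanFa(genome, gr)[[1]]))
  }
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome))
      stop("contig '", chrom, "' not found in genome", call. = FALSE)
    return(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
  }
  stop("genome must be a DNAStringSet, FaFile, or FASTA path", call. = FALSE)
}

genome_contig_length <- function(genome, chrom) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Rsamtools::FaFile(ensure_fai(genome))
  if (inherits(genome, "FaFile")) {
    idx <- Rsamtools::seqinfo(genome)
    if (!chrom %in% GenomeInfoDb::seqnames(idx))
      stop("contig '", chrom, "' not found in genome", call. = FALSE)
    return(GenomeInfoDb::seqlengths(idx)[[chrom]])
  }
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome))
      stop("contig '", chrom, "' not found in genome", call. = FALSE)
    return(length(genome[[chrom]]))
  }
  stop("genome must be a DNAStringSet, FaFile, or FASTA path", call. = FALSE)
}

# index a FASTA next to itself, or in a tempdir copy if not writable
ensure_fai <- function(path) {
  if (file.exists(paste0(path, ".fai"))) return(path)
  ok <- tryCatch({ Rsamtools::indexFa(path); TRUE },
                 error = function(e) FALSE)
  if (ok) return(path)
  tmp <- file.path(tempdir(), basename(path))
  file.copy(path, tmp, overwrite = TRUE)
  Rsamtools::indexFa(tmp)
  tmp
}

#' Read a genome FASTA into memory
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet` named by contig (first word of each
#'   header).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract the flanking sequence around an SNV
#'
#' Pulls `flank` nt of genomic context on each side of the variant (61 nt
#' total at the default 30). The genome base at the variant position must
#' equal the record's ref allele — a mismatch is a hard error, because silent
#' coordinate drift is the worst failure mode of this kind of pipeline.
#'
#' For `create_c_to_t` the editable base is the reference C: ref C puts the
#' target on the plus strand, ref G on the minus strand. For
#' `correct_t_to_c` the pathogenic alt allele (the C to revert) is first
#' substituted into the sequence, and the strand is chosen so the
#' substituted base reads C. The returned sequence is always reported on the
#' plus strand; strand-aware views are computed downstream.
#'
#' @param genome `DNAStringSet`, `Rsamtools::FaFile`, or FASTA path.
#' @param record a `variant_record`.
#' @param edit_class result of [classify_edit()] (computed when missing).
#' @param flank half-width in nt (default 30).
#' @return A `flanked_target`; when the window is truncated at a contig
#'   boundary a warning is raised and the offset reflects the truncation.
#' @export
extract_flank <- function(genome, record, edit_class = NULL, flank = 30L) {
  if (is.null(edit_class)) edit_class <- classify_edit(record)
  if (edit_class == "not_applicable")
    stop("cannot extract a flank for a not_applicable variant (",
         record$variant_id, ")", call. = FALSE)
  flank <- as.integer(flank)
  clen <- genome_contig_length(genome, record$chrom)
  if (record$pos > clen)
    stop("position ", record$pos, " beyond contig '", record$chrom,
         "' length ", clen, call. = FALSE)
  start <- record$pos - flank
  end <- record$pos + flank
  if (start < 1L || end > clen) {
    warning("flank truncated at contig boundary for ", record$chrom, ":",
            record$pos, call. = FALSE)
    start <- max(1L, start); end <- min(clen, end)
  }
  seq <- toupper(genome_fetch(genome, record$chrom, start, end))
  offset <- record$pos - start          # 0-based index of the SNV base
  obs <- substr(seq, offset + 1L, offset + 1L)
  if (obs != record$ref_allele)
    stop("reference mismatch at ", record$chrom, ":", record$pos,
         ": genome has '", obs, "', record says '", record$ref_allele, "'",
         call. = FALSE)
  if (edit_class == "create_c_to_t") {
    base <- record$ref_allele
    applied <- FALSE
  } else {
    # correction mode: the patient allele (the C) is substituted in
    base <- record$alt_allele
    substr(seq, offset + 1L, offset + 1L) <- base
    applied <- TRUE
  }
  strand <- switch(base, C = "+", G = "-",
                   stop("editable base for ", record$variant_id, " is '",
                        base, "', not C or G: alleles inconsistent with ",
                        edit_class, call. = FALSE))
  ft <- flanked_target(seq, offset, strand, edited_sequence_applied = applied)
  ft$chrom <- record$chrom
  ft$genomic_start <- start              # 1-based genomic coord of seq[1]
  ft
}

#' Read SNVs from a VCF file
#'
#' Minimal VCF v4 reader for biallelic SNV rows; non-SNV rows are skipped
#' with a count. Classification falls back to ref/alt alleles since plain
#' VCF carries no ClinVar-style name (the ID column is kept as variant_id).
#'
#' @param path VCF path (uncompressed).
#' @return List of `variant_record`s with attribute `n_skipped`.
#' @export
read_vcf_snvs <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  out <- list(); skipped <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) { skipped <- skipped + 1L; next }
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T") ||
        ref == alt) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <-
      variant_record(f[1], as.integer(f[2]), ref, alt,
                     variant_id = if (f[3] == ".") NA_character_ else f[3])
  }
  if (skipped)
    warning(skipped, " non-SNV or malformed VCF row(s) skipped",
            call. = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}
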