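# Panel module: the patient-specific assay definition.
#
# A panel holds 1-15 amplicons, each defined by a forward/reverse primer pair,
# an insert interval on its contig, and exactly one target somatic variant.
# Internal coordinates are 0-based half-open; the TSV/BED/VCF interchange
# formats are 1-based as their standards require.

PANEL_TSV_COLS <- c("amplicon_id", "chrom", "insert_start", "insert_end",
                    "fwd_primer", "rev_primer", "variant_pos", "ref", "alt",
                    "gene", "priority_class", "origin_label")

#' Construct a patient-specific amplicon panel
#'
#' @param amplicons data.frame with one row per amplicon and columns
#'   `amplicon_id`, `chrom`, `insert_start`, `insert_end` (0-based half-open),
#'   `fwd_primer`, `rev_primer`, `variant_pos` (0-based), `ref`, `alt`,
#'   `gene`, `priority_class`, `origin_label`, and optionally `seq` (the full
#'   reference sequence of the amplicon contig).
#' @param patient_id Identifier of the patient the assay was designed for.
#' @param metadata Optional named list of provenance metadata.
#'
#' @return An object of class `ctdna_panel`.
#' @export
panel <- function(amplicons, patient_id = "patient", metadata = list()) {
  if (!is.data.frame(amplicons)) stop("'amplicons' must be a data.frame")
  if (!"seq" %in% names(amplicons)) amplicons$seq <- NA_character_
  missing_cols <- setdiff(PANEL_TSV_COLS, names(amplicons))
  if (length(missing_cols)) {
    stop("missing panel columns: ", paste(missing_cols, collapse = ", "))
  }
  amplicons <- amplicons[, c(PANEL_TSV_COLS, "seq")]
  obj <- structure(
    list(patient_id = patient_id, amplicons = amplicons, metadata = metadata),
    class = "ctdna_panel"
  )
  validate_panel(obj)
  obj
}

validate_panel <- function(p) {
  a <- p$amplicons
  n <- nrow(a)
  if (n < 1L || n > 15L) {
    stop("a panel must contain between 1 and 15 amplicons (got ", n, ")")
  }
  if (anyDuplicated(a$amplicon_id)) stop("duplicate amplicon ids")
  key <- paste(a$chrom, a$variant_pos, a$ref, a$alt)
  if (anyDuplicated(key)) stop("duplicate target variants (chrom,pos,ref,alt)")
  ins_len <- a$insert_end - a$insert_start
  if (any(ins_len < 60L | ins_len > 150L)) {
    stop("insert lengths must be within [60, 150] bp")
  }
  if (any(a$ref == a$alt)) stop("ref and alt alleles must differ")
  if (any(a$variant_pos < a$insert_start |
          a$variant_pos + nchar(a$ref) > a$insert_end)) {
    stop("target variants must lie strictly inside the insert")
  }
  invisible(p)
}

#' @export
print.ctdna_panel <- function(x, ...) {
  cat(sprintf("ctdna_panel: patient '%s', %d amplicons\n",
              x$patient_id, nrow(x$amplicons)))
  ins <- x$amplicons$insert_end - x$amplicons$insert_start
  cat(sprintf("  insert lengths %d-%d bp; variants: %s\n",
              min(ins), max(ins),
              paste(sprintf("%s %s>%s", x$amplicons$gene,
                            x$amplicons$ref, x$amplicons$alt),
                    collapse = ", ")))
  invisible(x)
}

#' Reference sequences of a panel
#'
#' @param p A `ctdna_panel` whose amplicons carry `seq`.
#' @return A [Biostrings::DNAStringSet] named by contig (`chrom`).
#' @export
panel_reference <- function(p) {
  if (anyNA(p$amplicons$seq)) {
    stop("panel carries no reference sequences; read them with 'read_panel(..., reference=)'")
  }
  Biostrings::DNAStringSet(setNames(p$amplicons$seq, p$amplicons$chrom))
}

#' Write / read a panel as tab-separated text
#'
#' The TSV interchange uses 1-based inclusive coordinates (`insert_start`,
#' `insert_end`, `variant_pos`); they are converted to the 0-based half-open
#' internal convention on read. Reference sequences travel separately as
#' FASTA.
#'
#' @param p A `ctdna_panel`.
#' @param path Output TSV path.
#' @param reference_path Optional FASTA path; when given, contig sequences are
#'   written alongside the TSV.
#' @return `write_panel` invisibly returns `path`; `read_panel` returns a
#'   `ctdna_panel`.
#' @export
write_panel <- function(p, path, reference_path = NULL) {
  a <- p$amplicons
  out <- a[, PANEL_TSV_COLS]
  out$insert_start <- out$insert_start + 1L   # 1-based inclusive start
  out$variant_pos <- out$variant_pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reference_path)) {
    Biostrings::writeXStringSet(panel_reference(p), reference_path)
  }
  invisible(path)
}

#' @param patient_id Patient identifier to attach on read.
#' @param reference Optional FASTA path with one record per panel contig.
#' @rdname write_panel
#' @export
read_panel <- function(path, patient_id = "patient", reference = NULL) {
  a <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(PANEL_TSV_COLS, names(a))
  if (length(missing_cols)) {
    stop("malformed panel TSV, missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("insert_start", "insert_end", "variant_pos")) {
    v <- suppressWarnings(as.integer(a[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed panel TSV: non-integer '%s' at line %s",
                   col, paste(bad + 1L, collapse = ",")))
    }
    a[[col]] <- v
  }
  bad <- which(a$variant_pos < 1L)
  if (length(bad)) {
    stop("malformed panel TSV: variant_pos must be >= 1 (1-based) at line ",
         paste(bad + 1L, collapse = ","))
  }
  a$insert_start <- a$insert_start - 1L   # to 0-based half-open
  a$variant_pos <- a$variant_pos - 1L
  if (!is.null(reference)) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    if (!all(a$chrom %in% names(ref))) {
      stop("reference FASTA is missing contigs: ",
           paste(setdiff(a$chrom, names(ref)), collapse = ", "))
    }
    a$seq <- as.character(ref[a$chrom])
  }
  panel(a, patient_id = patient_id)
}

#' Export panel inserts as BED and target variants as VCF
#'
#' @param p A `ctdna_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
panel_to_bed <- function(p, path) {
  a <- p$amplicons
  gr <- GenomicRanges::GRanges(
    a$chrom,
    IRanges::IRanges(start = a$insert_start + 1L, end = a$insert_end),
    name = a$amplicon_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname panel_to_bed
#' @export
panel_to_vcf <- function(p, path) {
  a <- p$amplicons
  gr <- GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(start = a$variant_pos + 1L,
                              width = nchar(a$ref))
  )
  names(gr) <- a$amplicon_id
  vcf <- VariantAnnotation::VCF(rowRanges = gr)
  VariantAnnotation::fixed(vcf) <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(a$ref),
    ALT = Biostrings::DNAStringSetList(as.list(a$alt)),
    QUAL = rep(NA_real_, nrow(a)),
    FILTER = rep("PASS", nrow(a))
  )
  VariantAnnotation::writeVcf(vcf, path)
  lines <- readLines(path)
  if (!any(grepl("^##fileformat", lines))) {   # writeVcf omits it w/o header
    writeLines(c("##fileformat=VCFv4.2", lines), path)
  }
  invisible(path)
}

#' Read an exclusion list of common population-variant sites
#'
#' Sites of common population variants are excluded from error-rate profiling
#' so germline polymorphism does not masquerade as sequencing error. Accepts
#' BED (0-based half-open) or VCF (1-based) by file extension.
#'
#' @param path Path to a `.bed` or `.vcf` file.
#' @return data.frame with columns `chrom` and `pos` (1-based positions).
#' @export
read_exclusion_sites <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
  } else if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- SummarizedExperiment::rowRanges(vcf)
  } else {
    stop("exclusion list must be .bed or .vcf")
  }
  pos <- unlist(mapply(seq, GenomicRanges::start(gr), GenomicRanges::end(gr),
                       SIMPLIFY = FALSE))
  chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::width(gr))
  unique(data.frame(chrom = chrom, pos = as.integer(pos)))
}

# consequence -> priority class c..f; class a (prior primer site) and b
# (disease-gene list) are decided from annotations, not consequence.
consequence_class <- function(consequence) {
  cls <- rep("f", length(consequence))
  cons <- tolower(consequence)
  cls[grepl("missense|inframe|frameshift|insertion|deletion|indel", cons)] <- "c"
  cls[grepl("splice", cons)] <- "d"
  cls[grepl("synonymous", cons)] <- "e"
  cls[grepl("utr|intron|intergenic|upstream|downstream", cons)] <- "f"
  cls
}

#' Rank candidate somatic variants for assay design
#'
#' Orders tumour-derived candidate variants by the design priority used for
#' personalised panels: (a) sites already amplified by a previously tested
#' primer pair, (b) variants in a user-supplied disease gene list, then by
#' consequence: (c) missense and short indels, (d) splice-site, (e) synonymous,
#' (f) UTR/intronic. The sort is stable (ties keep input order) and the
#' selection is truncated at `max_n` (at most 15 variants fit one multiplex).
#'
#' @param candidates data.frame with columns `gene` and `consequence`, plus
#'   any variant identification columns, one row per candidate.
#' @param prior_primer_sites Logical vector (length `nrow(candidates)`) or a
#'   character vector of genes/sites matched against `candidates$site` when
#'   present, marking variants covered by a previously tested primer pair.
#' @param disease_genes Character vector of genes associated with the disease
#'   (class b); the list is configuration, not hard-coded.
#' @param max_n Maximum number of variants to select (default 15).
#'
#' @return `candidates` reordered and truncated, with a `priority_class`
#'   column added.
#' @export
rank_variants <- function(candidates, prior_primer_sites = FALSE,
                          disease_genes = character(0), max_n = 15L) {
  if (nrow(candidates) == 0L) {
    candidates$priority_class <- character(0)
    return(candidates)
  }
  if (is.character(prior_primer_sites)) {
    stopifnot("site" %in% names(candidates))
    prior <- candidates$site %in% prior_primer_sites
  } else {
    prior <- rep_len(prior_primer_sites, nrow(candidates))
  }
  cls <- consequence_class(candidates$consequence)
  cls[candidates$gene %in% disease_genes] <- "b"
  cls[prior] <- "a"                       # prior-site flag dominates
  candidates$priority_class <- cls
  ord <- order(match(cls, letters[1:6]))  # stable: order() preserves ties
  out <- candidates[ord, , drop = FALSE]
  utils::head(out, max_n)
}

#' Tissue-VAF quality control of candidate amplicons
#'
#' Before plasma use, each amplicon is checked on the tumour/normal tissue
#' pair: amplicons whose variant is absent from the tumour (VAF 0), or whose
#' tumour VAF is less than `fold_threshold` times the normal-tissue VAF, are
#' dropped; zero depth in either tissue makes the amplicon unevaluable rather
#' than silently dropped.
#'
#' @param tumour_k,tumour_n Variant-supporting and total read counts in tumour
#'   tissue, one per amplicon.
#' @param normal_k,normal_n Same for matched normal tissue.
#' @param fold_threshold Minimum tumour/normal VAF ratio (default 2).
#' @param min_depth Minimum tissue read depth for verification (default 100).
#'
#' @return data.frame with per-amplicon `tumour_vaf`, `normal_vaf`, and
#'   `status` in `{"keep", "drop", "unevaluable"}`.
#' @export
qc_amplicons_by_tissue_vaf <- function(tumour_k, tumour_n, normal_k, normal_n,
                                       fold_threshold = 2, min_depth = 100L) {
  n <- length(tumour_k)
  stopifnot(length(tumour_n) == n, length(normal_k) == n,
            length(normal_n) == n)
  tv <- ifelse(tumour_n > 0, tumour_k / tumour_n, NA_real_)
  nv <- ifelse(normal_n > 0, normal_k / normal_n, NA_real_)
  status <- rep("keep", n)
  drop <- !is.na(tv) & (tv == 0 | (!is.na(nv) & tv < fold_threshold * nv))
  status[drop] <- "drop"
  status[tumour_n < min_depth | normal_n < min_depth] <- "unevaluable"
  data.frame(tumour_vaf = tv, normal_vaf = nv, status = status)
}
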