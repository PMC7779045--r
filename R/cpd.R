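# Compensated pathogenic deviations: human pathogenic alternative residues
# observed as the wild-type residue in non-human orthologs whose local
# sequence context matches the human protein.

#' Map a human protein position to an alignment column
#'
#' @param aln a \code{protein_alignment}.
#' @param position 1-based position in the ungapped reference (human) sequence.
#' @return 1-based alignment column index holding that residue.
#' @export
position_to_column <- function(aln, position) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!is.numeric(position) || position < 1 || position != round(position))
    stop("position must be a positive integer, got ", position, call. = FALSE)
  ref <- strsplit(reference_seq(aln), "")[[1L]]
  nongap <- which(ref != GAP)
  if (position > length(nongap))
    stop("position ", position, " beyond the reference sequence (length ",
         length(nongap), ")", call. = FALSE)
  nongap[position]
}

#' Ungapped reference length
#' @param aln a \code{protein_alignment}.
#' @return number of non-gap residues in the reference row.
#' @export
reference_length <- function(aln) {
  sum(strsplit(reference_seq(aln), "")[[1L]] != GAP)
}

#' Flank identity of an ortholog around a human position
#'
#' Counts, among the 5 human residues upstream and 5 downstream of
#' \code{position} (in human ungapped coordinates), how many of the
#' corresponding alignment columns carry the identical residue in the target
#' record. Window slots falling beyond either protein terminus count as
#' non-identical, as does a gap in the target at a flank column.
#'
#' @param aln a \code{protein_alignment}.
#' @param record_index row index of the target record.
#' @param position 1-based human ungapped position of the variant.
#' @param flank number of positions on each side (default 5).
#' @return integer count in \code{0:(2 * flank)}.
#' @export
flank_identity <- function(aln, record_index, position, flank = 5L) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (record_index < 1L || record_index > length(aln$ids))
    stop("record_index out of range", call. = FALSE)
  href <- strsplit(reference_seq(aln), "")[[1L]]
  targ <- strsplit(aln$seqs[record_index], "")[[1L]]
  nongap <- which(href != GAP)
  n <- length(nongap)
  if (position < 1L || position > n)
    stop("position ", position, " beyond the reference sequence", call. = FALSE)
  slots <- setdiff(seq(position - flank, position + flank), position)
  valid <- slots[slots >= 1L & slots <= n]
  cols <- nongap[valid]
  sum(targ[cols] != GAP & targ[cols] == href[cols])
}

#' Variant record constructor
#'
#' @param gene gene name (e.g. \code{"MT-ND1"}).
#' @param position 1-based position in the human protein.
#' @param ref_aa,alt_aa single reference/alternative residue codes (must differ).
#' @param label free-form clinical label (default \code{"pathogenic"}).
#' @return a one-row data frame of class \code{variant_record}.
#' @export
variant_record <- function(gene, position, ref_aa, alt_aa,
                           label = "pathogenic") {
  ref_aa <- toupper(ref_aa); alt_aa <- toupper(alt_aa)
  if (position < 1) stop("position must be >= 1", call. = FALSE)
  if (ref_aa == alt_aa) stop("ref_aa and alt_aa must differ", call. = FALSE)
  v <- data.frame(gene = gene, position = as.integer(position),
                  ref_aa = ref_aa, alt_aa = alt_aa, label = label,
                  stringsAsFactors = FALSE)
  class(v) <- c("variant_record", class(v))
  v
}

#' Read a variant table
#' @param path TSV with columns gene, position, ref_aa, alt_aa and optionally
#'   label.
#' @return data frame of variants.
#' @export
read_variants <- function(path) {
  if (is.character(path) && !file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(v$label)) v$label <- "pathogenic"
  v
}

non_human_rows <- function(aln, reference_species = NULL) {
  if (is.null(reference_species)) reference_species <- aln$species[aln$ref]
  which(aln$species != reference_species & seq_along(aln$ids) != aln$ref)
}

#' Fraction of non-human orthologs carrying the alternative residue
#'
#' @param aln a filtered \code{protein_alignment}.
#' @param variant a \code{variant_record} (or one-row data frame with the same
#'   columns).
#' @param reference_species species string marking the human rows (default:
#'   the species of the reference record).
#' @return fraction of non-human records whose residue at the variant column
#'   equals \code{alt_aa}.
#' @export
cpd_prevalence <- function(aln, variant, reference_species = NULL) {
  col <- check_variant_column(aln, variant)
  rows <- non_human_rows(aln, reference_species)
  if (length(rows) == 0L) return(0)
  res <- substr(aln$seqs[rows], col, col)
  mean(res == variant$alt_aa)
}

check_variant_column <- function(aln, variant) {
  col <- position_to_column(aln, variant$position)
  obs <- substr(reference_seq(aln), col, col)
  if (obs != variant$ref_aa)
    stop("reference residue mismatch for ", variant$gene, " position ",
         variant$position, ": human alignment carries '", obs,
         "', variant table says '", variant$ref_aa, "'", call. = FALSE)
  col
}

#' Call a compensated pathogenic deviation
#'
#' A variant is a CPD when at least one non-human ortholog carries the human
#' alternative residue as its wild-type residue at the variant column and at
#' least \code{min_flank} of the ten human flanking residues (five per side)
#' are identical in that ortholog.
#'
#' @inheritParams cpd_prevalence
#' @param min_flank minimum flank identity (default 7 of 10).
#' @return \code{NULL} when the variant is not a CPD; otherwise a list of class
#'   \code{cpd_call} with elements \code{variant}, \code{supporting_species}
#'   (data frame: identifier, species, flank_identity) and
#'   \code{ortholog_fraction}.
#' @export
call_cpd <- function(aln, variant, min_flank = 7L, reference_species = NULL) {
  col <- check_variant_column(aln, variant)
  rows <- non_human_rows(aln, reference_species)
  if (length(rows) == 0L) return(NULL)
  res <- substr(aln$seqs[rows], col, col)
  carriers <- rows[res == variant$alt_aa]
  if (length(carriers) == 0L) return(NULL)
  fl <- vapply(carriers, flank_identity, 0L, aln = aln,
               position = variant$position)
  ok <- fl >= min_flank
  if (!any(ok)) return(NULL)
  support <- data.frame(identifier = aln$ids[carriers[ok]],
                        species = aln$species[carriers[ok]],
                        flank_identity = fl[ok], stringsAsFactors = FALSE)
  structure(list(variant = variant, supporting_species = support,
                 ortholog_fraction = length(carriers) / length(rows)),
            class = "cpd_call")
}

#' @export
print.cpd_call <- function(x, ...) {
  v <- x$variant
  cat(sprintf("CPD %s:p.%s%d%s  (%.1f%% of orthologs carry the alternative)\n",
              v$gene, v$ref_aa, v$position, v$alt_aa,
              100 * x$ortholog_fraction))
  cat("  supported by:", paste(x$supporting_species$species, collapse = "; "),
      "\n")
  invisible(x)
}

#' Screen a variant table for CPDs
#'
#' @param aln a filtered \code{protein_alignment} for one protein.
#' @param variants data frame of variants (see \code{read_variants}); rows
#'   whose \code{gene} differs from \code{aln$protein} are skipped.
#' @inheritParams call_cpd
#' @return data frame with one row per called CPD: gene, position, ref_aa,
#'   alt_aa, label, n_support, species (semicolon-joined), identifiers,
#'   max_flank_identity, ortholog_fraction.
#' @export
screen_cpds <- function(aln, variants, min_flank = 7L,
                        reference_species = NULL) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    if (!is.null(aln$protein) && !is.na(v$gene) && v$gene != aln$protein &&
        aln$protein != "protein") return(NULL)
    call <- call_cpd(aln, v, min_flank = min_flank,
                     reference_species = reference_species)
    if (is.null(call)) return(NULL)
    data.frame(gene = v$gene, position = v$position, ref_aa = v$ref_aa,
               alt_aa = v$alt_aa, label = v$label,
               n_support = nrow(call$supporting_species),
               species = paste(call$supporting_species$species,
                               collapse = "; "),
               identifiers = paste(call$supporting_species$identifier,
                                   collapse = "; "),
               max_flank_identity = max(call$supporting_species$flank_identity),
               ortholog_fraction = call$ortholog_fraction,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(gene = character(), position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      label = character(), n_support = integer(),
                      species = character(), identifiers = character(),
                      max_flank_identity = integer(),
                      ortholog_fraction = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
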