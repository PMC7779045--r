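# 20 canonical residues; '-' is the gap symbol. 'X' and other ambiguity codes
# are tolerated on input and treated as ordinary (never-matching-anything-else)
# symbols by the distance computations, but the scorers bin them with the gap.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
GAP <- "-"

#' Construct a protein alignment
#'
#' An ordered set of aligned ortholog sequences with one row designated as
#' the (human) reference. All sequences must have equal length; identifiers
#' must be unique.
#'
#' @param ids character vector of unique record identifiers.
#' @param seqs character vector of aligned sequences (equal lengths, residues
#'   plus \code{"-"}); uppercased on construction.
#' @param species character vector of species names, one per record.
#' @param reference_id identifier (or unique substring of one identifier) of
#'   the reference record.
#' @param protein optional protein name carried along for reporting.
#' @return an object of class \code{protein_alignment}: a list with elements
#'   \code{ids}, \code{species}, \code{seqs}, \code{ref} (reference row index)
#'   and \code{protein}.
#' @export
protein_alignment <- function(ids, seqs, species, reference_id,
                              protein = "protein") {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  species <- as.character(species)
  if (length(ids) == 0L) stop("alignment has no records", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("ragged alignment: record '", bad, "' has length ",
         nchar(seqs[ids == bad][1L]), ", expected ", lens[1L], call. = FALSE)
  }
  if (length(species) != length(ids))
    stop("species must have one entry per record", call. = FALSE)
  ref <- find_reference(ids, reference_id)
  structure(list(ids = ids, species = species, seqs = seqs,
                 ref = ref, protein = protein),
            class = "protein_alignment")
}

find_reference <- function(ids, reference_id) {
  hit <- which(ids == reference_id)
  if (length(hit) == 0L) hit <- grep(reference_id, ids, fixed = TRUE)
  if (length(hit) == 0L)
    stop("reference '", reference_id, "' not found among record identifiers",
         call. = FALSE)
  if (length(hit) > 1L)
    stop("reference '", reference_id, "' matches several records", call. = FALSE)
  hit
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", x$protein, "\n")
  cat(" ", length(x$ids), "records x", n_columns(x), "columns; reference:",
      x$ids[x$ref], paste0("(", x$species[x$ref], ")"), "\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln a \code{protein_alignment}.
#' @return integer column count.
#' @export
n_columns <- function(aln) nchar(aln$seqs[1L])

#' @export
as.matrix.protein_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Reference (human) row of an alignment
#' @param aln a \code{protein_alignment}.
#' @return the aligned reference sequence as a single string.
#' @export
reference_seq <- function(aln) aln$seqs[aln$ref]

#' Read an aligned FASTA file
#'
#' Headers are parsed into an identifier (the full header line) and a species
#' name. By default the species is taken as the two tokens following the
#' first whitespace-separated token (\code{"accession Genus species ..."});
#' supply \code{species_pattern} to override (first capture group is used).
#'
#' @param path path to an aligned FASTA file.
#' @param reference_id identifier (or unique substring) of the reference row.
#' @param protein protein name to attach (default: file name without extension).
#' @param species_pattern optional regular expression with one capture group
#'   applied to each header to extract the species name.
#' @return a \code{protein_alignment}.
#' @export
read_alignment <- function(path, reference_id, protein = NULL,
                           species_pattern = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("not readable as FASTA: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- names(set)
  seqs <- as.character(set)
  species <- vapply(ids, parse_species, "", pattern = species_pattern)
  if (is.null(protein))
    protein <- sub("\\.[^.]*$", "", basename(path))
  protein_alignment(ids, seqs, species, reference_id, protein = protein)
}

parse_species <- function(header, pattern = NULL) {
  if (!is.null(pattern)) {
    m <- regmatches(header, regexec(pattern, header))[[1L]]
    return(if (length(m) >= 2L) m[2L] else header)
  }
  toks <- strsplit(trimws(header), "[ \t]+")[[1L]]
  if (length(toks) >= 3L) paste(toks[2L], toks[3L])
  else if (length(toks) == 2L) toks[2L]
  else toks[1L]
}

#' Write an alignment to FASTA
#' @param aln a \code{protein_alignment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

#' Pairwise dissimilarity between two aligned sequences
#'
#' Fraction of compared columns at which the two rows differ. Columns gapped
#' in both rows are excluded from the denominator; a gap aligned to a residue
#' counts as a difference.
#'
#' @param a,b aligned sequences of equal length (strings or character vectors).
#' @return a fraction in \[0, 1\] (\code{NaN} if no column is comparable).
#' @export
dissimilarity <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1L]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1L]] else toupper(b)
  if (length(av) != length(bv))
    stop("sequences have unequal aligned lengths (", length(av), " vs ",
         length(bv), ")", call. = FALSE)
  compared <- !(av == GAP & bv == GAP)
  if (!any(compared)) return(NaN)
  sum(av[compared] != bv[compared]) / sum(compared)
}

#' Discard divergent orthologs
#'
#' Removes records whose dissimilarity to the reference exceeds
#' \code{max_dissimilarity} (strictly; records exactly at the threshold are
#' kept). The reference row is always retained and record order is preserved.
#' The per-record report is attached as attribute \code{"filter_report"}
#' (identifier, species, dissimilarity, kept).
#'
#' @param aln a \code{protein_alignment}.
#' @param max_dissimilarity maximum tolerated dissimilarity, in (0, 1\].
#' @return the filtered \code{protein_alignment}.
#' @export
filter_orthologs <- function(aln, max_dissimilarity = 0.5) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!(max_dissimilarity > 0 && max_dissimilarity <= 1))
    stop("max_dissimilarity must be in (0, 1]", call. = FALSE)
  href <- reference_seq(aln)
  d <- vapply(aln$seqs, dissimilarity, 0, b = href, USE.NAMES = FALSE)
  keep <- d <= max_dissimilarity
  keep[aln$ref] <- TRUE
  report <- data.frame(identifier = aln$ids, species = aln$species,
                       dissimilarity = d, kept = keep,
                       stringsAsFactors = FALSE)
  out <- protein_alignment(aln$ids[keep], aln$seqs[keep], aln$species[keep],
                           aln$ids[aln$ref], protein = aln$protein)
  attr(out, "filter_report") <- report
  out
}

#' Write an ortholog filter report
#' @param aln a \code{protein_alignment} returned by \code{filter_orthologs}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(aln, path) {
  rep <- attr(aln, "filter_report")
  if (is.null(rep)) stop("alignment carries no filter report", call. = FALSE)
  rep$status <- ifelse(rep$kept, "kept", "discarded")
  utils::write.table(rep[c("identifier", "species", "dissimilarity", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
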