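# Energetic compensation calls from free-energy-change tables. A single
# variant is disruptive when |ddG| strictly exceeds 0.61 kcal/mol; a double
# mutant is compensatory when its |ddG| is strictly below 0.1 kcal/mol. A
# compensation event requires a disruptive constituent and a compensatory
# pair.

DDG_SINGLE_CUTOFF <- 0.61  # kcal/mol, exceeded strictly => disruptive
DDG_PAIR_CUTOFF <- 0.1     # kcal/mol, undercut strictly => compensatory

#' Classify a single-mutant free-energy change
#'
#' @param ddg free-energy change in kcal/mol (vectorised).
#' @param cutoff magnitude that must be exceeded strictly (default 0.61).
#' @return character vector, \code{"disruptive"} or \code{"tolerated"}.
#' @export
classify_single <- function(ddg, cutoff = DDG_SINGLE_CUTOFF) {
  if (any(!is.finite(ddg)))
    stop("ddg must be finite", call. = FALSE)
  ifelse(abs(ddg) > cutoff, "disruptive", "tolerated")
}

#' Classify a double-mutant free-energy change
#'
#' @param ddg_pair free-energy change of the double mutant in kcal/mol
#'   (vectorised).
#' @param cutoff magnitude that must be undercut strictly (default 0.1).
#' @return character vector, \code{"compensatory"} or \code{"non-compensatory"}.
#' @export
classify_pair <- function(ddg_pair, cutoff = DDG_PAIR_CUTOFF) {
  if (any(!is.finite(ddg_pair)))
    stop("ddg_pair must be finite", call. = FALSE)
  ifelse(abs(ddg_pair) < cutoff, "compensatory", "non-compensatory")
}

#' Mean free-energy change over replicas
#' @param replicas numeric vector of per-replica ddG values (kcal/mol).
#' @return their arithmetic mean.
#' @export
mean_replicas <- function(replicas) {
  if (length(replicas) == 0L) stop("no replicas supplied", call. = FALSE)
  if (any(!is.finite(replicas))) stop("replicas must be finite", call. = FALSE)
  mean(replicas)
}

#' Read a ddG table
#'
#' Expects a TSV with variant identity columns and either a \code{ddg} column
#' or replica columns named \code{replica1}, \code{replica2}, ... (in which
#' case \code{ddg} is their row mean). Single tables carry protein, position,
#' ref_aa, alt_aa; double tables carry the same plus protein_b, position_b,
#' ref_aa_b, alt_aa_b.
#'
#' @param path input TSV.
#' @return data frame with a \code{ddg} column.
#' @export
read_ddg_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  reps <- grep("^replica[0-9]+$", names(d), value = TRUE)
  if (is.null(d$ddg)) {
    if (length(reps) == 0L)
      stop("ddG table needs a 'ddg' column or replica columns", call. = FALSE)
    d$ddg <- rowMeans(d[reps])
  }
  d
}

variant_id <- function(protein, position, ref_aa, alt_aa) {
  paste0(protein, ":p.", ref_aa, position, alt_aa)
}

#' Screen variant pairs for energetic compensation
#'
#' Joins each double mutant to the single-mutant ddG values of its two
#' constituents, classifies all three free-energy changes, and reports a
#' compensation event when at least one constituent is disruptive and the
#' double mutant is compensatory. Pairs are partitioned into
#' \code{interface} (both positions in \code{interface_residues}),
#' \code{inter} (different proteins) and \code{intra} (same protein).
#'
#' @param singles data frame of single mutants: protein, position, ref_aa,
#'   alt_aa, ddg.
#' @param doubles data frame of double mutants: protein, position, ref_aa,
#'   alt_aa, protein_b, position_b, ref_aa_b, alt_aa_b, ddg.
#' @param interface_residues optional data frame (protein, position) of
#'   interface residues; empty by default.
#' @param single_cutoff,pair_cutoff classification cutoffs in kcal/mol.
#' @return data frame with one row per double: the pair identity, single and
#'   pair ddG values and calls, \code{epistasis}
#'   (\code{ddg_pair - ddg_a - ddg_b}), \code{klass} and
#'   \code{compensation_event}.
#' @export
compensation_screen <- function(singles, doubles,
                                interface_residues = NULL,
                                single_cutoff = DDG_SINGLE_CUTOFF,
                                pair_cutoff = DDG_PAIR_CUTOFF) {
  sid <- variant_id(singles$protein, singles$position, singles$ref_aa,
                    singles$alt_aa)
  id_a <- variant_id(doubles$protein, doubles$position, doubles$ref_aa,
                     doubles$alt_aa)
  id_b <- variant_id(doubles$protein_b, doubles$position_b, doubles$ref_aa_b,
                     doubles$alt_aa_b)
  ma <- match(id_a, sid); mb <- match(id_b, sid)
  if (anyNA(ma) || anyNA(mb)) {
    missing <- unique(c(id_a[is.na(ma)], id_b[is.na(mb)]))
    stop("double mutants reference singles absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ddg_a <- singles$ddg[ma]; ddg_b <- singles$ddg[mb]
  call_a <- classify_single(ddg_a, single_cutoff)
  call_b <- classify_single(ddg_b, single_cutoff)
  pair_call <- classify_pair(doubles$ddg, pair_cutoff)
  iface <- logical(nrow(doubles))
  if (!is.null(interface_residues) && nrow(interface_residues)) {
    key <- paste(interface_residues$protein, interface_residues$position)
    iface <- paste(doubles$protein, doubles$position) %in% key &
      paste(doubles$protein_b, doubles$position_b) %in% key
  }
  klass <- ifelse(iface, "interface",
                  ifelse(doubles$protein != doubles$protein_b,
                         "inter", "intra"))
  data.frame(variant_a = id_a, variant_b = id_b,
             ddg_a = ddg_a, ddg_b = ddg_b, ddg_pair = doubles$ddg,
             call_a = call_a, call_b = call_b, pair_call = pair_call,
             epistasis = doubles$ddg - ddg_a - ddg_b,
             klass = klass,
             compensation_event = (call_a == "disruptive" |
                                     call_b == "disruptive") &
               pair_call == "compensatory",
             stringsAsFactors = FALSE)
}

#' Read an interface residue set
#' @param path two-column TSV (protein, position).
#' @return data frame with columns protein and position.
#' @export
read_interface <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("protein", "position") %in% names(d)))
    stop("interface table needs columns protein and position", call. = FALSE)
  d
}
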