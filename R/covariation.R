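# Co-variation scoring over ortholog alignments. Two independent scorers are
# provided: weighted mutual information with average-product correction
# (MI_APC) and mean-field direct coupling analysis (mfDCA, scored by direct
# information). Both operate on the 21-symbol alphabet (20 residues + gap);
# mfDCA removes the gap state as the reference symbol during the mean-field
# inversion, the standard gauge choice.

# integer state matrix: residues 1..20, gap/other 21
aln_state_matrix <- function(aln) {
  m <- as.matrix(aln)
  idx <- match(m, AA20)
  idx[is.na(idx)] <- 21L
  matrix(as.integer(idx), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Redundancy-correcting sequence weights
#'
#' Each record is weighted by the reciprocal of the number of records (itself
#' included) within \code{identity_threshold} fractional identity of it,
#' identity being measured over all alignment columns (gaps compare as
#' ordinary symbols). The effective number of sequences
#' \eqn{M_{eff} = \sum_s w_s} is attached as attribute \code{"Meff"}.
#'
#' @param aln a \code{protein_alignment}.
#' @param identity_threshold fractional identity above which two records count
#'   as redundant (default 0.8).
#' @return numeric vector of weights, one per record.
#' @export
sequence_weights <- function(aln, identity_threshold = 0.8) {
  M <- aln_state_matrix(aln)
  n <- nrow(M); L <- ncol(M)
  sim <- matrix(0, n, n)
  for (a in seq_len(21L)) {
    Ia <- (M == a) * 1
    sim <- sim + tcrossprod(Ia)
  }
  id <- sim / L
  w <- 1 / rowSums(id >= identity_threshold)
  names(w) <- aln$ids
  attr(w, "Meff") <- sum(w)
  w
}

# per-column (protein, human position) map; NA position for human-gap columns
column_map <- function(aln) {
  href <- strsplit(reference_seq(aln), "")[[1L]]
  segs <- segments_of(aln)
  pos <- rep(NA_integer_, length(href))
  prot <- rep(NA_character_, length(href))
  for (k in seq_len(nrow(segs))) {
    cols <- segs$start[k]:segs$end[k]
    nong <- cols[href[cols] != GAP]
    pos[nong] <- seq_along(nong)
    prot[cols] <- segs$protein[k]
  }
  data.frame(column = seq_along(href), protein = prot, position = pos,
             stringsAsFactors = FALSE)
}

segments_of <- function(aln) {
  if (!is.null(aln$segments)) return(aln$segments)
  data.frame(protein = aln$protein, start = 1L, end = n_columns(aln),
             stringsAsFactors = FALSE)
}

#' Concatenate per-protein alignments by species
#'
#' Joins one sequence per species per protein, in the order given. Only
#' species present in every input are retained. When a species contributes
#' several rows to one input (paralogs/duplicates), the row with the lowest
#' dissimilarity to that input's reference is used; the reference row itself
#' always represents the reference species.
#'
#' @param alns a named list of \code{protein_alignment}s (names become segment
#'   protein names; unnamed inputs use their own \code{protein} field).
#' @return a \code{concat_alignment} (also a \code{protein_alignment}) with a
#'   \code{segments} data frame (protein, start, end; 1-based inclusive
#'   columns).
#' @export
concatenate_alignments <- function(alns) {
  if (length(alns) < 2L) stop("need at least two alignments", call. = FALSE)
  nm <- names(alns)
  if (is.null(nm)) nm <- rep("", length(alns))
  nm <- ifelse(nzchar(nm), nm,
               vapply(alns, function(a) a$protein, ""))
  ref_species <- alns[[1L]]$species[alns[[1L]]$ref]
  sp_lists <- lapply(alns, function(a) unique(a$species))
  shared <- Reduce(intersect, sp_lists)
  if (!ref_species %in% shared)
    stop("reference species '", ref_species,
         "' is not present in every alignment", call. = FALSE)
  if (length(shared) == 0L)
    stop("no species shared by all alignments", call. = FALSE)
  # order: reference first, then first alignment's order
  shared <- c(ref_species,
              setdiff(unique(alns[[1L]]$species)[
                unique(alns[[1L]]$species) %in% shared], ref_species))

  pick_row <- function(a, sp) {
    if (sp == a$species[a$ref]) return(a$ref)
    rows <- which(a$species == sp)
    if (length(rows) == 1L) return(rows)
    d <- vapply(a$seqs[rows], dissimilarity, 0, b = reference_seq(a),
                USE.NAMES = FALSE)
    rows[which.min(d)]  # which.min is stable: first minimum wins
  }
  pieces <- lapply(alns, function(a)
    vapply(shared, function(sp) a$seqs[pick_row(a, sp)], ""))
  seqs <- do.call(paste0, pieces)
  widths <- vapply(alns, n_columns, 0L)
  end <- cumsum(widths)
  segments <- data.frame(protein = nm,
                         start = c(1L, utils::head(end, -1L) + 1L),
                         end = end, stringsAsFactors = FALSE)
  out <- protein_alignment(ids = shared, seqs = seqs, species = shared,
                           reference_id = ref_species,
                           protein = paste(nm, collapse = "+"))
  out$segments <- segments
  class(out) <- c("concat_alignment", class(out))
  out
}

new_score_matrix <- function(method, scores, aln, params) {
  cm <- column_map(aln)
  structure(list(method = method, scores = scores,
                 segments = segments_of(aln), column_map = cm,
                 params = params),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", x$method, "over", ncol(x$scores), "columns;",
      nrow(x$segments), "segment(s)\n")
  invisible(x)
}

# weighted one-hot indicators, one n x 21 matrix per column
one_hot_columns <- function(M) {
  n <- nrow(M)
  lapply(seq_len(ncol(M)), function(j) {
    I <- matrix(0, n, 21L)
    I[cbind(seq_len(n), M[, j])] <- 1
    I
  })
}

#' Mutual information with average-product correction
#'
#' Pairwise mutual information (bits) between alignment columns over the
#' 21-symbol alphabet, computed from sequence-weighted frequencies with a
#' uniform pseudocount, then average-product corrected:
#' \eqn{MI_p(i,j) = MI(i,j) - \bar{MI}(i)\,\bar{MI}(j)/\bar{MI}}, with row
#' means taken over \eqn{j \ne i}. The uncorrected matrix is kept in the
#' result as element \code{raw}.
#'
#' @param aln a \code{protein_alignment} (possibly concatenated).
#' @param pseudocount total pseudocount mass added to the weighted counts
#'   (default 0.01); use 0 for exact small-case arithmetic.
#' @param weights optional per-record weights (default
#'   \code{sequence_weights(aln)}).
#' @return a \code{score_matrix} with \code{method = "MI_APC"}; the corrected
#'   scores are in \code{$scores} (diagonal \code{NA}) and the uncorrected
#'   mutual information in \code{$raw}.
#' @export
mi_apc <- function(aln, pseudocount = 0.01, weights = NULL) {
  M <- aln_state_matrix(aln)
  L <- ncol(M)
  if (L < 2L) stop("need at least two alignment columns", call. = FALSE)
  if (is.null(weights)) weights <- sequence_weights(aln)
  w <- as.numeric(weights)
  W <- sum(w)
  q <- 21L
  I <- one_hot_columns(M)
  Iw <- lapply(I, function(x) x * w)
  ci <- lapply(Iw, colSums)
  pi_ <- lapply(ci, function(x) (x + pseudocount / q) / (W + pseudocount))
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      pij <- (crossprod(Iw[[i]], I[[j]]) + pseudocount / q^2) /
        (W + pseudocount)
      pp <- outer(pi_[[i]], pi_[[j]])
      nz <- pij > 0
      mi[i, j] <- mi[j, i] <- sum(pij[nz] * log2(pij[nz] / pp[nz]))
    }
  }
  mip <- apc_correct(mi)
  diag(mi) <- NA_real_
  out <- new_score_matrix("MI_APC", mip, aln,
                          params = list(pseudocount = pseudocount,
                                        Meff = attr(weights, "Meff")))
  out$raw <- mi
  out
}

# average-product correction; diagonal excluded from the means and set NA
apc_correct <- function(s) {
  L <- ncol(s)
  diag(s) <- NA_real_
  rmean <- rowMeans(s, na.rm = TRUE)
  gmean <- mean(s[upper.tri(s)])
  corr <- s - outer(rmean, rmean) / gmean
  diag(corr) <- NA_real_
  corr
}

#' Mean-field direct coupling analysis
#'
#' Standard mean-field DCA: sequence-weighted single and pair frequencies with
#' a uniform pseudocount, connected-correlation matrix over the 20 residue
#' states per column (the gap state is the removed reference symbol), coupling
#' matrix as the negative inverse, and per-pair direct information from a
#' two-site model whose fields are fit so that the direct distribution matches
#' the single-site marginals. Direct information is reported in nats and is
#' non-negative.
#'
#' @param aln a \code{protein_alignment} (possibly concatenated).
#' @param pseudocount_weight fraction of the total probability mass given to
#'   the uniform pseudocount (default 0.5, the field-standard choice).
#' @param weights optional per-record weights (default
#'   \code{sequence_weights(aln)}).
#' @return a \code{score_matrix} with \code{method = "mfDCA"} and direct
#'   information scores (diagonal \code{NA}).
#' @export
mfdca <- function(aln, pseudocount_weight = 0.5, weights = NULL) {
  M <- aln_state_matrix(aln)
  n <- nrow(M); L <- ncol(M)
  if (L < 2L) stop("need at least two alignment columns", call. = FALSE)
  if (!(pseudocount_weight > 0 && pseudocount_weight < 1))
    stop("pseudocount_weight must be in (0, 1)", call. = FALSE)
  if (is.null(weights)) weights <- sequence_weights(aln)
  w <- as.numeric(weights)
  Meff <- sum(w)
  if (Meff <= 1) stop("effective sequence number must exceed 1", call. = FALSE)
  q <- 21L
  lambda <- pseudocount_weight / (1 - pseudocount_weight) * Meff
  denom <- lambda + Meff

  # one-hot over all L*q states
  Ifull <- matrix(0, n, L * q)
  Ifull[cbind(rep(seq_len(n), L),
              (rep(seq_len(L), each = n) - 1L) * q + as.vector(M))] <- 1
  Iw <- Ifull * w
  fi <- (colSums(Iw) + lambda / q) / denom          # length L*q, sums to L
  Fij <- (crossprod(Iw, Ifull) + lambda / q^2) / denom
  # diagonal blocks carry the single-site distribution on their diagonal
  for (i in seq_len(L)) {
    blk <- ((i - 1L) * q + 1L):(i * q)
    Fij[blk, blk] <- diag(fi[blk])
  }
  C <- Fij - tcrossprod(fi)
  keep <- rep(seq_len(q) != q, L)                    # drop gap (reference) state
  C <- C[keep, keep]
  J <- tryCatch(-solve(C), error = function(e)
    stop("correlation matrix is numerically singular; raise ",
         "pseudocount_weight (", conditionMessage(e), ")", call. = FALSE))

  fi_site <- matrix(fi, nrow = q)                    # q x L single-site freqs
  di <- matrix(0, L, L)
  qr <- q - 1L
  for (i in seq_len(L - 1L)) {
    bi <- ((i - 1L) * qr + 1L):(i * qr)
    for (j in (i + 1L):L) {
      bj <- ((j - 1L) * qr + 1L):(j * qr)
      e <- matrix(0, q, q)
      e[seq_len(qr), seq_len(qr)] <- J[bi, bj]
      di[i, j] <- di[j, i] <- direct_information(exp(e), fi_site[, i],
                                                 fi_site[, j])
    }
  }
  diag(di) <- NA_real_
  new_score_matrix("mfDCA", di, aln,
                   params = list(pseudocount_weight = pseudocount_weight,
                                 Meff = Meff))
}

# two-site model: fit compatible fields by fixed point, then KL of the direct
# distribution against the product of single-site marginals
direct_information <- function(W, Pi, Pj, tol = 1e-9, max_iter = 2000L) {
  q <- length(Pi)
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  for (it in seq_len(max_iter)) {
    s1 <- as.vector(W %*% mu2)
    new1 <- Pi / s1; new1 <- new1 / sum(new1)
    s2 <- as.vector(crossprod(W, new1))
    new2 <- Pj / s2; new2 <- new2 / sum(new2)
    delta <- max(abs(new1 - mu1), abs(new2 - mu2))
    mu1 <- new1; mu2 <- new2
    if (delta < tol) break
  }
  Pdir <- W * outer(mu1, mu2)
  Pdir <- Pdir / sum(Pdir)
  pp <- outer(Pi, Pj)
  nz <- Pdir > 0
  max(0, sum(Pdir[nz] * log(Pdir[nz] / pp[nz])))
}

#' Highest-scoring column pairs
#'
#' Ranks distinct unordered column pairs by score and maps them back to
#' (protein, 1-based human position) through the score matrix's segments.
#' Columns that are gaps in the human reference never enter the ranking. Ties
#' are broken deterministically by (protein_a, position_a, protein_b,
#' position_b), proteins ordered as in the segments table.
#'
#' @param m a \code{score_matrix}.
#' @param n number of pairs to keep (default 500); all pairs are returned when
#'   fewer exist.
#' @return data frame of class \code{covarying_pairs}: protein_a, position_a,
#'   protein_b, position_b, method, score, klass (NA until filtered).
#' @export
top_pairs <- function(m, n = 500L) {
  stopifnot(inherits(m, "score_matrix"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  cm <- m$column_map
  ok <- which(!is.na(cm$position))
  if (length(ok) < 2L) stop("fewer than two rankable columns", call. = FALSE)
  idx <- t(utils::combn(ok, 2L))
  prot_rank <- stats::setNames(seq_len(nrow(m$segments)), m$segments$protein)
  sc <- m$scores[idx]
  pa <- cm$protein[idx[, 1L]]; pb <- cm$protein[idx[, 2L]]
  qa <- cm$position[idx[, 1L]]; qb <- cm$position[idx[, 2L]]
  # orient each pair so side a sorts first
  swap <- prot_rank[pa] > prot_rank[pb] |
    (prot_rank[pa] == prot_rank[pb] & qa > qb)
  tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  tmpq <- qa[swap]; qa[swap] <- qb[swap]; qb[swap] <- tmpq
  tmpc <- idx[swap, 1L]; idx[swap, 1L] <- idx[swap, 2L]; idx[swap, 2L] <- tmpc
  ord <- order(-sc, prot_rank[pa], qa, prot_rank[pb], qb)
  keep <- ord[seq_len(min(n, length(ord)))]
  out <- data.frame(protein_a = pa[keep], position_a = qa[keep],
                    protein_b = pb[keep], position_b = qb[keep],
                    column_a = idx[keep, 1L], column_b = idx[keep, 2L],
                    method = m$method, score = sc[keep],
                    klass = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("covarying_pairs", class(out))
  out
}

#' Keep inter-protein pairs
#'
#' Retains pairs whose two residues fall in different proteins and labels
#' them \code{klass = "inter"}.
#'
#' @param pairs a \code{covarying_pairs} data frame.
#' @return the filtered data frame.
#' @export
filter_inter <- function(pairs) {
  out <- pairs[pairs$protein_a != pairs$protein_b, , drop = FALSE]
  if (nrow(out)) out$klass <- "inter"
  rownames(out) <- NULL
  out
}

#' Keep intra-protein pairs outside the concatenation partner
#'
#' Retains pairs whose two residues fall in the same protein, excluding any
#' pair with a residue in \code{concat_protein} (the protein concatenated to
#' every run, MT-ND1 by default); labels them \code{klass = "intra"}.
#'
#' @param pairs a \code{covarying_pairs} data frame.
#' @param concat_protein name of the concatenated carrier protein.
#' @return the filtered data frame.
#' @export
filter_intra <- function(pairs, concat_protein = "MT-ND1") {
  sel <- pairs$protein_a == pairs$protein_b &
    pairs$protein_a != concat_protein & pairs$protein_b != concat_protein
  out <- pairs[sel, , drop = FALSE]
  if (nrow(out)) out$klass <- "intra"
  rownames(out) <- NULL
  out
}

pair_key <- function(pairs) {
  paste(pairs$protein_a, pairs$position_a, pairs$protein_b, pairs$position_b,
        sep = "|")
}

#' Combine pair lists from two methods
#'
#' The union keeps every row of both inputs (a pair found by both methods
#' appears once per method and is flagged \code{in_common}); the common list
#' holds one row per pair found by both methods, matched on the unordered
#' (protein, position) pair identity.
#'
#' @param a,b \code{covarying_pairs} data frames from two methods.
#' @return list with elements \code{union} and \code{common}.
#' @export
combine_methods <- function(a, b) {
  ka <- pair_key(a); kb <- pair_key(b)
  u <- rbind(a, b)
  u$in_common <- pair_key(u) %in% intersect(ka, kb)
  common <- a[ka %in% kb, , drop = FALSE]
  if (nrow(common)) {
    common$method <- paste(unique(c(a$method, b$method)), collapse = "+")
    common$score_b <- b$score[match(pair_key(common), kb)]
  }
  rownames(u) <- NULL; rownames(common) <- NULL
  list(union = u, common = common)
}

#' Write a score matrix with a self-describing header
#'
#' The TSV carries a \code{#}-prefixed header block (method, parameters,
#' segments) followed by the symmetric score matrix with column labels
#' \code{protein:column}; \code{read_score_matrix} round-trips it.
#'
#' @param m a \code{score_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# method=", m$method), con)
  pv <- vapply(m$params, function(x) format(x, digits = 15), "")
  writeLines(paste0("# params=", paste(names(m$params), pv, sep = ":",
                                       collapse = ";")), con)
  writeLines(paste0("# segments=",
                    paste(m$segments$protein, m$segments$start,
                          m$segments$end, sep = ":", collapse = ";")), con)
  writeLines(paste0("# positions=",
                    paste(ifelse(is.na(m$column_map$position), ".",
                                 m$column_map$position), collapse = ",")), con)
  lab <- paste0(m$column_map$protein, ":", m$column_map$column)
  writeLines(paste(c("column", lab), collapse = "\t"), con)
  sc <- m$scores
  for (i in seq_len(nrow(sc)))
    writeLines(paste(c(lab[i], format(sc[i, ], digits = 15, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a score matrix written by \code{write_score_matrix}
#' @param path input path.
#' @return a \code{score_matrix}.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           hdr[startsWith(hdr, paste0("# ", key, "="))][1L])
  method <- get("method")
  params <- list()
  pstr <- get("params")
  if (nzchar(pstr)) {
    for (kv in strsplit(pstr, ";")[[1L]]) {
      p <- strsplit(kv, ":")[[1L]]
      params[[p[1L]]] <- as.numeric(p[2L])
    }
  }
  seg <- do.call(rbind, lapply(strsplit(strsplit(get("segments"),
                                                 ";")[[1L]], ":"),
                               function(x) data.frame(protein = x[1L],
                                                      start = as.integer(x[2L]),
                                                      end = as.integer(x[3L]),
                                                      stringsAsFactors = FALSE)))
  posv <- strsplit(get("positions"), ",")[[1L]]
  pos <- suppressWarnings(as.integer(ifelse(posv == ".", NA, posv)))
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  sc <- as.matrix(tab)
  dimnames(sc) <- NULL
  cm <- data.frame(column = seq_len(ncol(sc)),
                   protein = vapply(strsplit(colnames(tab), ":"),
                                    `[`, "", 1L),
                   position = pos, stringsAsFactors = FALSE)
  structure(list(method = method, scores = sc, segments = seg,
                 column_map = cm, params = params),
            class = "score_matrix")
}

#' Read a raw I-COMS score matrix
#'
#' Adapter for externally produced square score matrices: a delimited file
#' whose first row and first column carry matching labels of the form
#' \code{protein_position} (separator configurable via \code{label_pattern},
#' which must capture protein and position). The resulting object can be fed
#' to \code{top_pairs} directly.
#'
#' @param path matrix file.
#' @param method method name to record (e.g. \code{"cMI"} or \code{"mfDCA"}).
#' @param sep field separator (default tab).
#' @param label_pattern regex with two capture groups (protein, position)
#'   applied to the labels; default \code{"^(.+)[_:]([0-9]+)$"}.
#' @return a \code{score_matrix}.
#' @export
read_icoms_matrix <- function(path, method, sep = "\t",
                              label_pattern = "^(.+)[_:]([0-9]+)$") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  sc <- as.matrix(tab)
  if (nrow(sc) != ncol(sc))
    stop("I-COMS matrix is not square: ", path, call. = FALSE)
  lab <- colnames(tab)
  m <- regmatches(lab, regexec(label_pattern, lab))
  bad <- vapply(m, length, 0L) < 3L
  if (any(bad))
    stop("unparseable column label(s): ", paste(lab[bad][1:min(3, sum(bad))],
                                                collapse = ", "), call. = FALSE)
  prot <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  dimnames(sc) <- NULL
  sc <- (sc + t(sc)) / 2          # enforce symmetry against dialect round-off
  diag(sc) <- NA_real_
  cm <- data.frame(column = seq_along(lab), protein = prot, position = pos,
                   stringsAsFactors = FALSE)
  segs <- do.call(rbind, lapply(unique(prot), function(p) {
    cols <- which(prot == p)
    data.frame(protein = p, start = min(cols), end = max(cols),
               stringsAsFactors = FALSE)
  }))
  structure(list(method = method, scores = sc, segments = segs,
                 column_map = cm, params = list(source = "icoms")),
            class = "score_matrix")
}

#' Recompute pair totals from a directory of I-COMS matrices
#'
#' Scans \code{bundle_dir} for score-matrix files whose names carry a method
#' token (\code{cMI}/\code{mfDCA}, case-insensitive), applies the TOP-\code{n}
#' selection and the inter/intra filters to each run, and aggregates the
#' de-duplicated pair totals per method, their union and their intersection,
#' for the inter- and intra-protein classes separately.
#'
#' @param bundle_dir directory holding the raw matrices (TSV, I-COMS dialect).
#' @param top_n pairs retained per run and method (default 500).
#' @param concat_protein the protein concatenated to every run (default
#'   \code{"MT-ND1"}).
#' @return list with per-class counts: \code{inter} and \code{intra}, each a
#'   list of \code{cmi}, \code{mfdca}, \code{union} (sum of the two),
#'   \code{common}, plus the pair tables themselves.
#' @export
reproduce_icoms_counts <- function(bundle_dir, top_n = 500L,
                                   concat_protein = "MT-ND1") {
  if (!dir.exists(bundle_dir))
    stop("bundle directory not found: ", bundle_dir, call. = FALSE)
  files <- list.files(bundle_dir, pattern = "\\.(tsv|txt|csv|mat)$",
                      full.names = TRUE, recursive = TRUE)
  method_of <- function(f) {
    if (grepl("mfdca|dca", basename(f), ignore.case = TRUE)) "mfDCA"
    else if (grepl("cmi|mi", basename(f), ignore.case = TRUE)) "cMI"
    else NA_character_
  }
  meths <- vapply(files, method_of, "")
  files <- files[!is.na(meths)]; meths <- meths[!is.na(meths)]
  if (length(files) == 0L)
    stop("no cMI/mfDCA matrix files found under ", bundle_dir, call. = FALSE)
  collect <- function(method, klass) {
    res <- lapply(files[meths == method], function(f) {
      m <- read_icoms_matrix(f, method = method)
      tp <- top_pairs(m, n = top_n)
      if (klass == "inter") filter_inter(tp)
      else filter_intra(tp, concat_protein = concat_protein)
    })
    out <- do.call(rbind, res)
    out[!duplicated(pair_key(out)), , drop = FALSE]
  }
  summarise <- function(klass) {
    a <- collect("cMI", klass); b <- collect("mfDCA", klass)
    cb <- combine_methods(a, b)
    list(cmi = nrow(a), mfdca = nrow(b), union = nrow(a) + nrow(b),
         common = nrow(cb$common), pairs = cb$union)
  }
  list(inter = summarise("inter"), intra = summarise("intra"))
}

#' Write a pair list as TSV
#' @param pairs a \code{covarying_pairs} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ranking AUC of planted pairs
#'
#' Area under the ROC curve for separating labelled-positive items from the
#' rest by score (Mann-Whitney form); used to judge how well a scorer ranks
#' planted coupled pairs above background.
#'
#' @param scores numeric scores.
#' @param positive logical vector, \code{TRUE} for planted items.
#' @return AUC in \[0, 1\].
#' @export
ranking_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- which(positive); neg <- which(!positive)
  if (!length(pos) || !length(neg))
    stop("need both positive and negative items", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
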