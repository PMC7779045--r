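# Simulators that plant known signal: ortholog alignments with fixed
# "pathogenic" residues (CPDs) and co-substituting column pairs, ddG tables
# with an exactly known compensated fraction, and harmonic-mode trajectories
# with a known eigenvalue spectrum. All are deterministic for a fixed seed.

#' Simulate a star-phylogeny ortholog alignment with planted signal
#'
#' Tip sequences descend independently from the reference (human) row, each
#' column substituting with probability \eqn{1 - e^{-divergence}} to a
#' uniformly drawn different residue. Coupled column pairs co-substitute: with
#' probability \code{strength} a species' pair state is drawn jointly (column
#' j deterministically mapped from column i through a fixed random residue
#' permutation), otherwise the two columns evolve independently. CPD carriers
#' receive the alternative residue at the planted position, with exactly
#' \code{round(10 * flank_conservation)} of their ten human-flank slots held
#' identical to human and the remainder forced different, so flank-identity
#' margins are unambiguous. Non-carrier rows never show the planted
#' alternative residue, so carrier prevalence and recovery are exact.
#'
#' @param n_species total rows including the human reference (first row).
#' @param length number of columns.
#' @param divergence expected substitutions per site on each tip branch.
#' @param coupled_pairs optional data frame (i, j, strength) of planted
#'   coupled column pairs; columns must be distinct and within \code{length}.
#' @param cpd_specs optional list of planted variants, each a list with
#'   position, ref_aa, alt_aa, n_carriers, flank_conservation.
#' @param seed integer seed (deterministic output).
#' @param protein protein name for the alignment (default \code{"SIM-P1"}).
#' @return list with \code{alignment} (a \code{protein_alignment}; row 1 is
#'   "Homo sapiens") and \code{truth} (seed, human sequence, planted pairs
#'   with their residue maps, planted CPDs with carrier identifiers).
#' @export
simulate_alignment <- function(n_species, length, divergence = 0.6,
                               coupled_pairs = NULL, cpd_specs = NULL,
                               seed = 1L, protein = "SIM-P1") {
  if (n_species < 2L) stop("need at least two species", call. = FALSE)
  if (!is.null(cpd_specs)) {
    if (!is.null(cpd_specs$position)) cpd_specs <- list(cpd_specs)
    for (sp in cpd_specs) {
      if (sp$n_carriers >= n_species)
        stop("n_carriers must be smaller than n_species", call. = FALSE)
      if (sp$position < 1L || sp$position > length)
        stop("planted CPD position outside the sequence", call. = FALSE)
      if (toupper(sp$ref_aa) == toupper(sp$alt_aa))
        stop("planted ref_aa and alt_aa must differ", call. = FALSE)
    }
  }
  if (!is.null(coupled_pairs)) {
    with_bad <- coupled_pairs$i == coupled_pairs$j |
      pmax(coupled_pairs$i, coupled_pairs$j) > length
    if (any(with_bad))
      stop("coupled columns must be distinct and within the length",
           call. = FALSE)
  }
  set.seed(seed)
  human <- sample(AA20, length, replace = TRUE)
  if (!is.null(cpd_specs))
    for (sp in cpd_specs) human[sp$position] <- toupper(sp$ref_aa)

  p_sub <- 1 - exp(-divergence)
  n_tips <- n_species - 1L
  tips <- matrix(rep(human, each = n_tips), nrow = n_tips)
  if (n_tips > 0L && p_sub > 0) {
    hit <- matrix(stats::runif(n_tips * length) < p_sub, n_tips, length)
    for (j in seq_len(length)) {
      rows <- which(hit[, j])
      if (!base::length(rows)) next
      alt <- sample(setdiff(AA20, human[j]), base::length(rows),
                    replace = TRUE)
      tips[rows, j] <- alt
    }
  }

  pair_truth <- NULL
  if (!is.null(coupled_pairs) && nrow(coupled_pairs)) {
    maps <- vector("list", nrow(coupled_pairs))
    for (k in seq_len(nrow(coupled_pairs))) {
      i <- coupled_pairs$i[k]; j <- coupled_pairs$j[k]
      strength <- coupled_pairs$strength[k]
      sigma <- sample(AA20)                      # bijection residue(i)->residue(j)
      names(sigma) <- AA20
      # anchor the ancestral states so sigma(human_i) == human_j
      cur <- sigma[human[i]]
      swap_with <- names(sigma)[sigma == human[j]]
      sigma[swap_with] <- cur
      sigma[human[i]] <- human[j]
      joint <- stats::runif(n_tips) < strength
      subbed <- stats::runif(n_tips) < p_sub
      for (s in seq_len(n_tips)) {
        if (joint[s]) {
          a <- if (subbed[s]) sample(AA20, 1L) else human[i]
          tips[s, i] <- a
          tips[s, j] <- sigma[a]
        }
      }
      maps[[k]] <- list(i = i, j = j, strength = strength, sigma = sigma)
    }
    pair_truth <- maps
  }

  cpd_truth <- NULL
  if (!is.null(cpd_specs)) {
    cpd_truth <- vector("list", base::length(cpd_specs))
    for (k in seq_along(cpd_specs)) {
      sp <- cpd_specs[[k]]
      carriers <- sample(seq_len(n_tips), sp$n_carriers)
      # keep planting unambiguous: no non-carrier may show the alternative
      stray <- setdiff(which(tips[, sp$position] == toupper(sp$alt_aa)),
                       carriers)
      if (base::length(stray))
        tips[stray, sp$position] <- sample(setdiff(AA20, toupper(sp$alt_aa)),
                                           base::length(stray), replace = TRUE)
      flank <- setdiff(seq(sp$position - 5L, sp$position + 5L), sp$position)
      flank <- flank[flank >= 1L & flank <= length]
      n_ident <- min(round(10 * sp$flank_conservation), base::length(flank))
      for (s in carriers) {
        tips[s, sp$position] <- toupper(sp$alt_aa)
        ident <- if (n_ident > 0L) sample(flank, n_ident) else integer()
        for (j in flank) {
          if (j %in% ident) tips[s, j] <- human[j]
          else tips[s, j] <- sample(setdiff(AA20, human[j]), 1L)
        }
      }
      cpd_truth[[k]] <- list(position = sp$position,
                             ref_aa = toupper(sp$ref_aa),
                             alt_aa = toupper(sp$alt_aa),
                             flank_conservation = sp$flank_conservation,
                             carrier_rows = carriers + 1L)
    }
  }

  # headers carry the species ("accession Genus species") so FASTA round
  # trips re-derive the species under the default parsing convention
  species <- c("Homo sapiens", sprintf("Species sp%04d", seq_len(n_tips)))
  ids <- paste(c("sim0000", sprintf("sim%04d", seq_len(n_tips))), species)
  seqs <- c(paste(human, collapse = ""),
            apply(tips, 1L, paste, collapse = ""))
  aln <- protein_alignment(ids, seqs, species, "sim0000", protein = protein)
  if (!is.null(cpd_truth))
    cpd_truth <- lapply(cpd_truth, function(ct) {
      ct$carrier_ids <- ids[ct$carrier_rows]
      ct
    })
  truth <- list(seed = seed, divergence = divergence,
                human = paste(human, collapse = ""),
                planted_pairs = pair_truth, planted_cpds = cpd_truth)
  list(alignment = aln, truth = truth)
}

#' Simulate single/double ddG tables with an exactly planted compensated
#' fraction
#'
#' Exactly \code{round(fraction_compensated * n_pairs)} pairs are built as
#' compensation events: one constituent disruptive
#' (\eqn{|ddG| \ge 0.61 + margin_single}), the partner tolerated, and the
#' double mutant compensatory (\eqn{|ddG| \le 0.1 - margin_pair}). The
#' remaining pairs violate one rule each, alternating between "no disruptive
#' constituent" and "disruptive but non-compensatory pair". Replica values
#' are noisy but recentred so each record's mean equals its drawn ddG
#' exactly; \code{noise_sd} must stay well inside the margins.
#'
#' @param n_pairs number of variant pairs.
#' @param fraction_compensated planted fraction in \[0, 1\].
#' @param noise_sd replica standard deviation, kcal/mol (default 0.01).
#' @param seed integer seed.
#' @param n_replicas replicas per record (default 10).
#' @param margin_single,margin_pair classification margins, kcal/mol.
#' @param proteins two protein names for the pair sides.
#' @return list with \code{singles}, \code{doubles} (data frames with replica
#'   columns and \code{ddg}) and \code{truth} (seed and the logical
#'   \code{compensated} vector by pair index).
#' @export
simulate_ddg_table <- function(n_pairs, fraction_compensated,
                               noise_sd = 0.01, seed = 1L, n_replicas = 10L,
                               margin_single = 0.3, margin_pair = 0.05,
                               proteins = c("MT-ND3", "MT-ND1")) {
  if (fraction_compensated < 0 || fraction_compensated > 1)
    stop("fraction_compensated must be in [0, 1]", call. = FALSE)
  if (4 * noise_sd > min(margin_single, margin_pair))
    stop("noise_sd too large for the classification margins; lower it or ",
         "widen the margins", call. = FALSE)
  set.seed(seed)
  n_comp <- round(fraction_compensated * n_pairs)
  compensated <- rep(FALSE, n_pairs)
  if (n_comp > 0L) compensated[seq_len(n_comp)] <- TRUE

  draw_aa_pair <- function() sample(AA20, 2L)
  rows_s <- vector("list", 2L * n_pairs)
  rows_d <- vector("list", n_pairs)
  mode_flip <- TRUE
  for (t in seq_len(n_pairs)) {
    aa_a <- draw_aa_pair(); aa_b <- draw_aa_pair()
    if (compensated[t]) {
      ddg_a <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0.61 + margin_single, 2.5)
      ddg_b <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0, 0.61 - margin_single)
      ddg_p <- stats::runif(1L, -(0.1 - margin_pair), 0.1 - margin_pair)
    } else if (mode_flip) {
      # no disruptive constituent (pair ddG irrelevant; keep it small)
      ddg_a <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0, 0.61 - margin_single)
      ddg_b <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0, 0.61 - margin_single)
      ddg_p <- stats::runif(1L, -(0.1 - margin_pair), 0.1 - margin_pair)
      mode_flip <- FALSE
    } else {
      # disruptive constituent but clearly non-compensatory pair
      ddg_a <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0.61 + margin_single, 2.5)
      ddg_b <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0, 0.61 - margin_single)
      ddg_p <- sample(c(-1, 1), 1L) *
        stats::runif(1L, 0.1 + margin_pair, 2.0)
      mode_flip <- TRUE
    }
    rows_s[[2L * t - 1L]] <- data.frame(protein = proteins[1L], position = t,
                                        ref_aa = aa_a[1L], alt_aa = aa_a[2L],
                                        ddg = ddg_a, stringsAsFactors = FALSE)
    rows_s[[2L * t]] <- data.frame(protein = proteins[2L], position = t,
                                   ref_aa = aa_b[1L], alt_aa = aa_b[2L],
                                   ddg = ddg_b, stringsAsFactors = FALSE)
    rows_d[[t]] <- data.frame(protein = proteins[1L], position = t,
                              ref_aa = aa_a[1L], alt_aa = aa_a[2L],
                              protein_b = proteins[2L], position_b = t,
                              ref_aa_b = aa_b[1L], alt_aa_b = aa_b[2L],
                              ddg = ddg_p, stringsAsFactors = FALSE)
  }
  singles <- do.call(rbind, rows_s)
  doubles <- do.call(rbind, rows_d)
  add_replicas <- function(d) {
    reps <- t(vapply(d$ddg, function(mu) {
      r <- mu + stats::rnorm(n_replicas, 0, noise_sd)
      r - mean(r) + mu                       # replica mean is exactly ddg
    }, numeric(n_replicas)))
    colnames(reps) <- paste0("replica", seq_len(n_replicas))
    cbind(d[setdiff(names(d), "ddg")], as.data.frame(reps), ddg = d$ddg)
  }
  list(singles = add_replicas(singles), doubles = add_replicas(doubles),
       truth = list(seed = seed, compensated = compensated))
}

# uniformly random proper rotation
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Simulate a harmonic-mode trajectory with a known spectrum
#'
#' Atoms oscillate along orthonormal internal collective modes (drawn
#' orthogonal to the six rigid-body degrees of freedom, as physical normal
#' modes are) with integer numbers of cycles over the trajectory, so each
#' mode's sampled positional variance is exactly the squared amplitude;
#' isotropic Gaussian noise and an optional random rigid motion per frame are
#' added on top.
#'
#' @param n_frames number of frames (must exceed twice the mode count).
#' @param n_atoms number of atoms.
#' @param mode_amplitudes amplitudes (Angstrom) of the planted modes.
#' @param noise_sd isotropic coordinate noise (Angstrom, default 0).
#' @param rigid_drift apply a random rotation+translation to every frame.
#' @param seed integer seed.
#' @return list with \code{trajectory} and \code{truth} (seed, amplitudes,
#'   eigenvalues = squared amplitudes, modes as a 3N x k matrix).
#' @export
simulate_trajectory <- function(n_frames, n_atoms, mode_amplitudes = c(2, 1),
                                noise_sd = 0, rigid_drift = FALSE,
                                seed = 1L) {
  if (n_frames < 2L) stop("need at least two frames", call. = FALSE)
  k <- length(mode_amplitudes)
  if (k > 0L && n_frames <= 2L * k)
    stop("n_frames must exceed twice the number of modes", call. = FALSE)
  set.seed(seed)
  base <- matrix(stats::rnorm(n_atoms * 3L, sd = 5), n_atoms, 3L)
  basevec <- as.vector(base)                  # index j = atom + (coord-1)*n_atoms
  Q <- NULL
  flat <- matrix(rep(basevec, each = n_frames), n_frames)
  if (k > 0L) {
    # internal modes: orthonormal directions orthogonal to the 6 rigid-body
    # degrees of freedom of the base structure, so a least-squares
    # superposition cannot absorb any planted variance
    centred <- sweep(base, 2L, colMeans(base))
    rigid <- matrix(0, 3L * n_atoms, 6L)
    for (cc in 1:3)
      rigid[(cc - 1L) * n_atoms + seq_len(n_atoms), cc] <- 1
    axes <- diag(3L)
    for (cc in 1:3) {
      om <- axes[, cc]
      rot <- t(apply(centred, 1L, function(x) c(om[2] * x[3] - om[3] * x[2],
                                                om[3] * x[1] - om[1] * x[3],
                                                om[1] * x[2] - om[2] * x[1])))
      rigid[, 3L + cc] <- as.vector(rot)
    }
    QQ <- qr.Q(qr(cbind(rigid, matrix(stats::rnorm(3L * n_atoms * k),
                                      ncol = k))))
    Q <- QQ[, 6L + seq_len(k), drop = FALSE]
    tseq <- seq_len(n_frames) - 1L
    S <- vapply(seq_len(k), function(m)
      sqrt(2) * mode_amplitudes[m] * sin(2 * pi * m * tseq / n_frames),
      numeric(n_frames))
    flat <- flat + S %*% t(Q)
  }
  if (noise_sd > 0)
    flat <- flat + stats::rnorm(base::length(flat), 0, noise_sd)
  arr <- array(flat, c(n_frames, n_atoms, 3L))
  if (rigid_drift) {
    for (t in seq_len(n_frames)) {
      R <- random_rotation()
      shift <- stats::rnorm(3L, sd = 10)
      m <- arr[t, , ]
      dim(m) <- c(n_atoms, 3L)
      arr[t, , ] <- sweep(m %*% R, 2L, shift, "+")
    }
  }
  list(trajectory = trajectory(arr),
       truth = list(seed = seed, amplitudes = mode_amplitudes,
                    eigenvalues = sort(mode_amplitudes^2, decreasing = TRUE),
                    modes = Q))
}
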