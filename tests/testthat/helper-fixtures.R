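# Builders and independent oracles shared across the suite.

# small alignment straight from strings; first row is the human reference
toy_alignment <- function(seqs, ids = sprintf("seq%02d", seq_along(seqs)),
                          species = c("Homo sapiens",
                                      sprintf("Species sp%02d",
                                              seq_len(length(seqs) - 1L))),
                          protein = "TOY-P1") {
  protein_alignment(ids, seqs, species, ids[1L], protein = protein)
}

# a score_matrix built by hand (single protein, gapless reference)
make_score_matrix <- function(scores, protein = "TOY-P1",
                              positions = seq_len(ncol(scores)),
                              method = "MI_APC") {
  diag(scores) <- NA_real_
  structure(list(method = method, scores = scores,
                 segments = data.frame(protein = protein, start = 1L,
                                       end = ncol(scores),
                                       stringsAsFactors = FALSE),
                 column_map = data.frame(column = seq_len(ncol(scores)),
                                         protein = protein,
                                         position = positions,
                                         stringsAsFactors = FALSE),
                 params = list()),
            class = "score_matrix")
}

# random coding sequence of n_codons without stop codons (table 2)
random_toy_cds <- function(n_codons, seed) {
  set.seed(seed)
  code <- Biostrings::getGeneticCode("2")
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

toy_gene <- function(cds, name = "TOY-G1", start = 1L, strand = "+") {
  structure(list(name = name, cds = cds,
                 padded_cds = paste0(cds,
                                     c("", "AA", "A")[nchar(cds) %% 3L + 1L]),
                 genome_start = as.integer(start),
                 genome_end = as.integer(start + nchar(cds) - 1L),
                 strand = strand, translation_table = "2",
                 incomplete_stop = nchar(cds) %% 3L != 0L),
            class = "coding_gene")
}

# independent brute-force oracle: mutate every base, translate the whole CDS,
# and diff the protein strings (stop-involving changes excluded on request)
oracle_nonsyn_count <- function(cds, exclude_stops = TRUE) {
  code <- Biostrings::getGeneticCode("2")
  pad <- c("", "AA", "A")[nchar(cds) %% 3L + 1L]
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(paste0(s, pad)),
                          genetic.code = code, no.init.codon = TRUE)),
    "")[[1L]]
  ref_aa <- tr(cds)
  total <- 0L
  for (p in seq_len(nchar(cds))) {
    ref_nt <- substr(cds, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref_nt)) {
      mut <- cds
      substr(mut, p, p) <- alt
      alt_aa <- tr(mut)
      changed <- which(alt_aa != ref_aa)
      if (length(changed) == 0L) next
      stopifnot(length(changed) == 1L)
      if (exclude_stops &&
          (ref_aa[changed] == "*" || alt_aa[changed] == "*")) next
      total <- total + 1L
    }
  }
  total
}
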