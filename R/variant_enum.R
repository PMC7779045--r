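# Exhaustive enumeration of nonsynonymous single-nucleotide substitutions in
# the 13 mtDNA protein-coding genes under the vertebrate mitochondrial
# genetic code (NCBI translation table 2: TGA=Trp, ATA=Met, AGA/AGG=stop).

NUCS <- c("A", "C", "G", "T")

mito_code <- function(table = "2") Biostrings::getGeneticCode(table)

#' Load protein-coding genes from a genome and a gene table
#'
#' @param genome path to a single-record genome FASTA, or a
#'   \code{Biostrings::DNAString}/\code{DNAStringSet}.
#' @param gene_table path to a TSV (columns gene, start, end, strand) or an
#'   equivalent data frame; coordinates are 1-based inclusive on the given
#'   genome, strand is \code{"+"} or \code{"-"}.
#' @param translation_table NCBI genetic-code identifier (default \code{"2"},
#'   vertebrate mitochondrial).
#' @return list of \code{coding_gene} objects: name, cds (coding strand,
#'   unpadded), padded_cds (stop completed with \code{"A"}s when the feature
#'   ends mid-codon), genome_start, genome_end, strand, translation_table,
#'   incomplete_stop. Each gene is checked to translate without internal stop
#'   codons.
#' @export
load_genes <- function(genome, gene_table, translation_table = "2") {
  g <- genome
  if (is.character(g)) {
    if (!file.exists(g)) stop("no such genome file: ", g, call. = FALSE)
    g <- Biostrings::readDNAStringSet(g)
  }
  if (inherits(g, "DNAStringSet")) {
    if (length(g) != 1L)
      stop("genome FASTA must hold exactly one record", call. = FALSE)
    g <- g[[1L]]
  }
  tab <- gene_table
  if (is.character(tab))
    tab <- utils::read.table(tab, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) stop("gene table holds no CDS features", call. = FALSE)
  code <- mito_code(translation_table)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (r$start < 1L || r$end > length(g) || r$start > r$end)
      stop("coordinates of ", r$gene, " fall outside the genome", call. = FALSE)
    s <- Biostrings::subseq(g, r$start, r$end)
    if (r$strand == "-") s <- Biostrings::reverseComplement(s)
    cds <- as.character(s)
    rem <- nchar(cds) %% 3L
    incomplete <- rem != 0L
    padded <- if (rem == 1L) paste0(cds, "AA")
    else if (rem == 2L) paste0(cds, "A") else cds
    aa <- translate_cds(padded, code)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", body, fixed = TRUE))
      stop("gene ", r$gene, " contains an internal stop codon; check the ",
           "coordinates/strand", call. = FALSE)
    structure(list(name = r$gene, cds = cds, padded_cds = padded,
                   genome_start = as.integer(r$start),
                   genome_end = as.integer(r$end), strand = r$strand,
                   translation_table = translation_table,
                   incomplete_stop = incomplete),
              class = "coding_gene")
  })
}

translate_cds <- function(cds, code) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     genetic.code = code,
                                     no.init.codon = TRUE))
}

#' @export
print.coding_gene <- function(x, ...) {
  cat(sprintf("coding_gene %s: %d nt (%s strand, %d..%d)%s\n", x$name,
              nchar(x$cds), x$strand, x$genome_start, x$genome_end,
              if (x$incomplete_stop) ", incomplete stop (A-completed)" else ""))
  invisible(x)
}

#' The 13 human mtDNA protein-coding genes
#'
#' Loads the human mitochondrial genome record shipped with the seqinr
#' package (NC_001807.4, 16,571 bp) together with the package's verified CDS
#' coordinate table for that record. Any other genome/table pair (e.g. the
#' rCRS NC_012920.1 with its annotation) can be supplied to
#' \code{load_genes} directly instead.
#'
#' @return list of 13 \code{coding_gene} objects.
#' @export
human_mtdna_genes <- function() {
  fa <- system.file("sequences", "humanMito.fasta", package = "seqinr")
  tab <- system.file("extdata", "mtdna_genes_NC_001807.tsv",
                     package = "mitonet")
  if (!nzchar(fa)) stop("seqinr's humanMito.fasta not found", call. = FALSE)
  load_genes(fa, tab)
}

#' Enumerate nonsynonymous single-nucleotide substitutions in one gene
#'
#' Every complete codon of the coding sequence is subjected to all nine
#' single-nucleotide substitutions; a variant is emitted when the encoded
#' residue changes. Bases added to complete an incomplete terminal stop are
#' never enumerated. Under the default policy (\code{"exclude"}) substitutions
#' whose reference or alternative codon is a stop do not count as amino acid
#' variations; \code{"include"} counts stop gain/loss as changes too.
#'
#' @param gene a \code{coding_gene}.
#' @param stop_policy \code{"exclude"} (default) or \code{"include"}.
#' @return data frame: gene, genome_position, ref_nt, alt_nt (coding strand),
#'   codon_index, protein_position, ref_aa, alt_aa.
#' @export
enumerate_nonsyn <- function(gene, stop_policy = c("exclude", "include")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(gene, "coding_gene"))
  code <- mito_code(gene$translation_table)
  cds <- gene$padded_cds
  n_real <- nchar(gene$cds)
  ncod <- nchar(cds) %/% 3L
  out <- vector("list", ncod)
  for (k in seq_len(ncod)) {
    cod <- substr(cds, 3L * k - 2L, 3L * k)
    ref_aa <- unname(code[cod])
    if (stop_policy == "exclude" && ref_aa == "*") next
    rows <- list(); r <- 0L
    for (p in 1:3) {
      cds_pos <- 3L * (k - 1L) + p
      if (cds_pos > n_real) next            # padded base, never enumerated
      ref_nt <- substr(cod, p, p)
      for (alt in NUCS[NUCS != ref_nt]) {
        alt_cod <- cod
        substr(alt_cod, p, p) <- alt
        alt_aa <- unname(code[alt_cod])
        if (stop_policy == "exclude" && alt_aa == "*") next
        if (alt_aa == ref_aa) next
        r <- r + 1L
        rows[[r]] <- c(cds_pos, ref_nt, alt, ref_aa, alt_aa)
      }
    }
    if (r) out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(gene = character(), genome_position = integer(),
                      ref_nt = character(), alt_nt = character(),
                      codon_index = integer(), protein_position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  cds_pos <- as.integer(m[, 1L])
  gpos <- if (gene$strand == "+") gene$genome_start + cds_pos - 1L
  else gene$genome_end - cds_pos + 1L
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  data.frame(gene = gene$name, genome_position = gpos,
             ref_nt = m[, 2L], alt_nt = m[, 3L],
             codon_index = codon_index, protein_position = codon_index,
             ref_aa = m[, 4L], alt_aa = m[, 5L], stringsAsFactors = FALSE)
}

#' Total nonsynonymous variant count over a gene set
#'
#' Genes are enumerated independently, so a substitution inside an overlap of
#' two genes contributes once per gene.
#'
#' @param genes list of \code{coding_gene} objects.
#' @param stop_policy see \code{enumerate_nonsyn}.
#' @return integer total.
#' @export
total_count <- function(genes, stop_policy = c("exclude", "include")) {
  stop_policy <- match.arg(stop_policy)
  sum(vapply(genes, function(g) nrow(enumerate_nonsyn(g, stop_policy)), 0L))
}
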