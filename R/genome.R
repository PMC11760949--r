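#' Generate a synthetic annotated genome with controlled ApT content
#'
#' Builds an AT-rich random genome in which ApT dinucleotides occur *only* at
#' explicitly placed positions, so the set of ApT duplex sites (the 6mA motif
#' in *Tetrahymena*: an adenine on the Watson strand immediately followed by
#' thymine, pairing an adenine on each strand offset by 1 bp) is known exactly.
#' Non-overlapping gene models are packed onto each chromosome.
#'
#' All coordinates are 0-based, half-open. An ApT site is addressed by the
#' position of its Watson-strand adenine; the Crick-strand adenine of the same
#' duplex sits at position + 1.
#'
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (each chromosome; >= 1000).
#' @param n_genes total number of genes to place (split across chromosomes).
#' @param apt_density target ApT duplex density in sites per kb. `0` yields a
#'   genome with no ApT sites (downstream 6mApT/ApT is then undefined).
#' @param gene_len_range integer range of gene lengths (bp) sampled uniformly,
#'   ignored when `gene_lengths` is given.
#' @param gene_lengths optional explicit vector of gene lengths (bp), recycled
#'   across chromosomes in order; overrides `gene_len_range`.
#' @param base_probs background base composition (before ApT removal); the
#'   default mimics an AT-rich ciliate genome.
#'
#' @return An object of class `sim_genome`: a list with `chroms` (named list
#'   of character vectors, one base per element), `genes` (data.table:
#'   gene_id, chrom, start, end, strand, tss, tes) and `apt` (data.table:
#'   chrom, pos — Watson-strand adenine positions).
#' @export
make_genome <- function(seed, n_chrom = 1L, chrom_len = 50000L, n_genes = 10L,
                        apt_density = 100, gene_len_range = c(1500L, 2500L),
                        gene_lengths = NULL,
                        base_probs = c(A = 0.35, C = 0.125, G = 0.125, T = 0.40)) {
  chrom_len <- as.integer(chrom_len)
  if (chrom_len < 1000L) stopf("chrom_len must be >= 1000 bp")
  if (apt_density < 0) stopf("apt_density must be >= 0")
  n_chrom <- as.integer(n_chrom)
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    chroms <- list()
    genes <- list()
    apt <- list()
    # split genes across chromosomes as evenly as possible
    genes_per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1L)))
    gene_counter <- 0L
    for (ci in seq_len(n_chrom)) {
      ch <- sprintf("chr%d", ci)
      g <- sample(names(base_probs), chrom_len, replace = TRUE, prob = base_probs)
      # scrub accidental ApT dinucleotides: replace the T of any A->T pair;
      # iterate because a replacement can create a new pair with its neighbour
      for (iter in 1:100) {
        hit <- which(g[-chrom_len] == "A" & g[-1L] == "T")
        if (!length(hit)) break
        g[hit + 1L] <- sample(c("A", "C", "G"), length(hit), replace = TRUE)
      }
      if (length(which(g[-chrom_len] == "A" & g[-1L] == "T"))) {
        stopf("internal error: failed to scrub background ApT dinucleotides")
      }

      # place ApT sites on a stride-3 grid so sites never abut (each site
      # occupies positions p and p+1); grid positions are 0-based
      n_apt <- as.integer(round(apt_density * chrom_len / 1000))
      if (n_apt > 0L) {
        grid <- seq(2L, chrom_len - 4L, by = 3L)
        if (n_apt > length(grid)) {
          stopf("apt_density %.1f/kb exceeds what can be placed without overlap",
                apt_density)
        }
        p <- sort(sample(grid, n_apt))
        g[p + 1L] <- "A"   # 0-based p -> 1-based p+1
        g[p + 2L] <- "T"
      } else {
        p <- integer()
      }

      # pack genes with random inter-gene gaps
      ng <- genes_per_chrom[ci]
      if (ng > 0L) {
        lens <- if (!is.null(gene_lengths)) {
          as.integer(rep_len(gene_lengths, n_genes)[gene_counter + seq_len(ng)])
        } else {
          as.integer(round(runif(ng, gene_len_range[1], gene_len_range[2])))
        }
        slack <- chrom_len - sum(lens)
        if (slack < ng + 1L) {
          stopf("cannot pack %d genes totalling %d bp into %d bp", ng, sum(lens),
                chrom_len)
        }
        w <- -log(runif(ng + 1L))
        gaps <- floor(w / sum(w) * slack)
        starts <- if (ng == 1L) gaps[1L] else {
          cumsum(c(gaps[1L], lens[-ng] + gaps[seq.int(2L, ng)]))
        }
        strand <- sample(c("+", "-"), ng, replace = TRUE)
        genes[[ci]] <- data.table::data.table(
          gene_id = sprintf("g%03d", gene_counter + seq_len(ng)),
          chrom = ch, start = as.integer(starts),
          end = as.integer(starts + lens), strand = strand
        )
        gene_counter <- gene_counter + ng
      }
      chroms[[ch]] <- g
      apt[[ci]] <- data.table::data.table(chrom = ch, pos = as.integer(p))
    }

    genes <- data.table::rbindlist(genes)
    if (nrow(genes)) {
      genes[, tss := data.table::fifelse(strand == "+", start, end)]
      genes[, tes := data.table::fifelse(strand == "+", end, start)]
    } else {
      genes <- data.table::data.table(
        gene_id = character(), chrom = character(), start = integer(),
        end = integer(), strand = character(), tss = integer(), tes = integer()
      )
    }
    out <- structure(
      list(chroms = chroms, chrom_len = chrom_len,
           genes = genes, apt = data.table::rbindlist(apt)),
      class = "sim_genome"
    )
    validate_genome(out)
    out
  })
}

# Check the sim_genome invariants: ApT sites carry A then T, genes in bounds
# and non-overlapping.
validate_genome <- function(genome) {
  for (ch in names(genome$chroms)) {
    g <- genome$chroms[[ch]]
    p <- genome$apt[chrom == ch, pos]
    if (length(p)) {
      if (!all(g[p + 1L] == "A") || !all(g[p + 2L] == "T")) {
        stopf("ApT invariant violated on %s", ch)
      }
    }
    gs <- genome$genes[chrom == ch]
    if (nrow(gs)) {
      if (any(gs$start < 0L) || any(gs$end > length(g))) {
        stopf("gene out of chromosome bounds on %s", ch)
      }
      data.table::setorder(gs, start)
      if (nrow(gs) > 1L && any(gs$start[-1L] < gs$end[-nrow(gs)])) {
        stopf("overlapping genes on %s", ch)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s) x %d bp, %d genes, %d ApT sites\n",
              length(x$chroms), x$chrom_len, nrow(x$genes), nrow(x$apt)))
  invisible(x)
}

#' Write genome annotation to plain-text files
#'
#' Genes are written as BED6 (0-based half-open, score 0) and ApT sites as
#' BED3 single-base intervals at the Watson-strand adenine.
#'
#' @param genome a `sim_genome`.
#' @param genes_file,apt_file output paths (tab-separated, no headers).
#' @return invisibly, the paths written.
#' @export
write_genome_beds <- function(genome, genes_file, apt_file) {
  g <- genome$genes
  data.table::fwrite(
    g[, .(chrom, start, end, gene_id, score = 0L, strand)],
    genes_file, sep = "\t", col.names = FALSE
  )
  a <- genome$apt
  data.table::fwrite(
    a[, .(chrom, start = pos, end = pos + 1L)],
    apt_file, sep = "\t", col.names = FALSE
  )
  invisible(c(genes_file, apt_file))
}
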