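# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# their arguments and do not perturb the session RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed; keeps values in 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Columns of the long per-position molecule table used throughout the package.
MOLECULE_COLS <- c("molecule_id", "chrom", "start", "end", "passes",
                   "strand", "position", "base", "ipd_ratio")

empty_molecule_table <- function() {
  data.table::data.table(
    molecule_id = integer(), chrom = character(), start = integer(),
    end = integer(), passes = integer(), strand = character(),
    position = integer(), base = character(), ipd_ratio = numeric()
  )
}

assert_molecule_table <- function(molecules) {
  if (!is.data.frame(molecules)) {
    stopf("`molecules` must be a data.frame/data.table in long per-position form")
  }
  missing <- setdiff(MOLECULE_COLS, names(molecules))
  if (length(missing)) {
    stopf("`molecules` is missing columns: %s", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Resolve an `apt` argument: either a sim_genome or a table with chrom/pos.
resolve_apt <- function(apt) {
  if (inherits(apt, "sim_genome")) return(apt$apt)
  apt <- data.table::as.data.table(apt)
  if (!all(c("chrom", "pos") %in% names(apt))) {
    stopf("`apt` must be a sim_genome or a table with columns chrom, pos")
  }
  apt[, .(chrom = as.character(chrom), pos = as.integer(pos))]
}

# Resolve a `genes` argument: sim_genome or BED6-like table. Coordinates are
# 0-based half-open; tss/tes are derived from strand when absent.
resolve_genes <- function(genes) {
  if (inherits(genes, "sim_genome")) return(data.table::copy(genes$genes))
  g <- data.table::as.data.table(genes)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(g))
  if (length(missing)) {
    stopf("`genes` is missing columns: %s", paste(missing, collapse = ", "))
  }
  g[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(g$start >= g$end)) stopf("gene intervals must satisfy start < end")
  if (!"tss" %in% names(g)) g[, tss := data.table::fifelse(strand == "+", start, end)]
  if (!"tes" %in% names(g)) g[, tes := data.table::fifelse(strand == "+", end, start)]
  g[]
}

# Map positions onto non-overlapping gene intervals (0-based half-open).
# Returns the gene_id for each position, NA when intergenic.
assign_to_genes <- function(chroms, positions, genes) {
  out <- rep(NA_character_, length(positions))
  genes <- data.table::as.data.table(genes)
  for (ch in unique(chroms)) {
    gs <- genes[chrom == ch]
    if (!nrow(gs)) next
    data.table::setorder(gs, start)
    sel <- which(chroms == ch)
    idx <- findInterval(positions[sel], gs$start)
    ok <- idx > 0L & positions[sel] < gs$end[pmax(idx, 1L)]
    out[sel[ok]] <- gs$gene_id[idx[ok]]
  }
  out
}
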