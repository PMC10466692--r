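#' GRCh37 chromosome lengths (bp)
#'
#' Reference lengths of the 24 human chromosomes in the GRCh37 assembly,
#' used for parsing microarray (ISCN-style) findings printed in GRCh37
#' coordinates and for scaling the synthetic genome.
#'
#' @format Named numeric vector (`chr1` ... `chr22`, `chrX`, `chrY`).
#' @export
grch37_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

# First covered (binnable/array-probed) position per GRCh37 chromosome.
# Acrocentric p-arms (13, 14, 15, 21, 22) carry no probes or mappable bins;
# their callable span starts at the q-arm.
grch37_callable_start <- c(
  chr1 = 0, chr2 = 0, chr3 = 0, chr4 = 0, chr5 = 0, chr6 = 0, chr7 = 0,
  chr8 = 0, chr9 = 0, chr10 = 0, chr11 = 0, chr12 = 0,
  chr13 = 19020000, chr14 = 19000000, chr15 = 20000000,
  chr16 = 0, chr17 = 0, chr18 = 0, chr19 = 0, chr20 = 0,
  chr21 = 14300000, chr22 = 16000000, chrX = 0, chrY = 0
)

#' Callable (binned) length of a GRCh37 chromosome
#'
#' Length of the portion of a chromosome covered by analysis bins — the
#' denominator used when deciding whether an interval finding spans a whole
#' chromosome.
#'
#' @param chrom Chromosome name(s), `"chr21"` or `"21"` style.
#' @return Numeric vector of callable lengths in bp.
#' @export
grch37_callable_length <- function(chrom) {
  chrom <- norm_chrom(chrom)
  bad <- !(chrom %in% names(grch37_lengths))
  if (any(bad)) stopf("unknown chromosome: %s", chrom[bad][1])
  unname(grch37_lengths[chrom] - grch37_callable_start[chrom])
}

#' Normalise chromosome names to `chrN` form
#' @keywords internal
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Build a reduced synthetic genome
#'
#' Constructs a scaled-down stand-in for the human genome: every GRCh37
#' chromosome shrunk by `scale` and tiled with fixed-width bins carrying a
#' per-bin GC fraction. A 1/20-scale genome with 50-kb bins yields ~3,100
#' bins, small enough that a full plasma sample simulates in milliseconds
#' while keeping realistic relative chromosome sizes.
#'
#' @param scale Linear scale factor relative to GRCh37 (default 1/20).
#' @param bin_size Bin width in bp (default 50000).
#' @param gc_mean,gc_sd Mean and SD of the simulated per-bin GC fraction.
#' @param seed Integer seed fixing the GC landscape.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `gc`, of class `synthetic_genome`; attributes `bin_size`,
#'   `scale` and `seed`.
#' @examples
#' g <- synthetic_genome()
#' table(g$chrom)[["chr21"]]
#' @export
synthetic_genome <- function(scale = 1 / 20, bin_size = 5e4,
                             gc_mean = 0.41, gc_sd = 0.05, seed = 1L) {
  if (!is_scalar_number(scale) || scale <= 0) stopf("`scale` must be > 0")
  if (!is_scalar_number(bin_size) || bin_size <= 0) stopf("`bin_size` must be > 0")
  n_bins <- pmax(floor(grch37_lengths * scale / bin_size), 2)
  names(n_bins) <- names(grch37_lengths)
  chrom <- rep(names(n_bins), n_bins)
  start <- unlist(lapply(n_bins, function(k) (seq_len(k) - 1) * bin_size),
                  use.names = FALSE)
  gc <- with_seed(seed, {
    pmin(0.65, pmax(0.25, stats::rnorm(length(chrom), gc_mean, gc_sd)))
  })
  g <- data.frame(chrom = chrom, start = start, end = start + bin_size,
                  gc = gc, stringsAsFactors = FALSE)
  stopifnot(all(g$gc >= 0), all(g$gc <= 1), all(g$end > g$start))
  structure(g, bin_size = bin_size, scale = scale, seed = as.integer(seed),
            class = c("synthetic_genome", "data.frame"))
}

#' Chromosome lengths of a synthetic genome
#' @param genome A [synthetic_genome()].
#' @return Named numeric vector of binned chromosome lengths in bp.
#' @export
genome_chrom_lengths <- function(genome) {
  tapply(genome$end, genome$chrom, max)[unique(genome$chrom)]
}
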