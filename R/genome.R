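#' Construct a genome build table
#'
#' A genome build is the coordinate scaffold used throughout the package: an
#' ordered set of chromosomes with lengths and one centromere interval each.
#' Centromeres delimit the p and q arms and anchor the telomeric-allelic-
#' imbalance and large-scale-transition definitions.
#'
#' All coordinates in the package are 0-based, half-open.
#'
#' @param chromosomes Data frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (base pairs).
#' @param build Label for the build (free text, e.g. `"GRCh37"`).
#' @return A tibble of class `genome_build` with one row per chromosome and a
#'   `build` attribute.
#' @examples
#' genome_build(
#'   data.frame(chrom = "chr1", length = 100e6, cen_start = 45e6, cen_end = 48e6),
#'   build = "toy"
#' )
#' @export
genome_build <- function(chromosomes, build = "custom") {
  req <- c("chrom", "length", "cen_start", "cen_end")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols) > 0) {
    abort(paste0("genome table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  g <- as_tibble(chromosomes)[, req]
  g$chrom <- as.character(g$chrom)
  if (anyDuplicated(g$chrom)) abort("chromosome names must be unique.")
  if (any(g$length <= 0)) abort("chromosome lengths must be positive.")
  bad <- g$cen_start < 0 | g$cen_start >= g$cen_end | g$cen_end > g$length
  if (any(bad)) {
    abort(paste0("centromere interval must lie inside the chromosome: ",
                 paste(g$chrom[bad], collapse = ", ")))
  }
  structure(g, class = c("genome_build", class(g)), build = build)
}

#' Packaged GRCh37 genome build
#'
#' Chromosome lengths and centromere intervals for GRCh37 (hg19), shipped as
#' a plain TSV under `inst/extdata`. The centromere coordinate set is an
#' input, not a constant of the method: supply your own table through
#' [read_genome()] to use a different convention.
#'
#' @param autosomes_only Drop chrX/chrY (the scar scores ignore sex
#'   chromosomes by default anyway). Default `FALSE`.
#' @return A `genome_build` tibble.
#' @export
grch37_genome <- function(autosomes_only = FALSE) {
  path <- system.file("extdata", "grch37_genome.tsv", package = "hrdkit")
  g <- read_genome(path, build = "GRCh37")
  if (autosomes_only) {
    g2 <- g[!g$chrom %in% c("chrX", "chrY"), ]
    g <- structure(g2, class = class(g), build = attr(g, "build"))
  }
  g
}

#' Packaged toy genome build
#'
#' Three ~100-Mb chromosomes with mid-chromosome centromeres; used by the
#' examples and tests so the whole pipeline runs in seconds.
#'
#' @return A `genome_build` tibble.
#' @export
toy_genome <- function() {
  path <- system.file("extdata", "toy_genome.tsv", package = "hrdkit")
  read_genome(path, build = "toy")
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    abort(paste0("unknown chromosome: ",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  genome$length[i]
}

#' Chromosome arm of a genomic interval
#'
#' Classifies an interval as lying on the p arm (entirely left of the
#' centromere), the q arm (entirely right), or as spanning the centromere.
#' Exactly one label applies to any valid interval.
#'
#' @param chrom,start,end Interval coordinates (0-based, half-open);
#'   vectorised.
#' @param genome A [genome_build()].
#' @return Character vector with values `"p"`, `"q"` or `"spans-centromere"`.
#' @examples
#' g <- toy_genome()
#' arm_of("chrA", 0, 30e6, g)
#' arm_of("chrA", 50e6, 70e6, g)
#' @export
arm_of <- function(chrom, start, end, genome) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    abort(paste0("unknown chromosome: ",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  if (any(start < 0 | start >= end | end > genome$length[i])) {
    abort("interval must satisfy 0 <= start < end <= chromosome length.")
  }
  cs <- genome$cen_start[i]
  ce <- genome$cen_end[i]
  ifelse(end <= cs, "p", ifelse(start >= ce, "q", "spans-centromere"))
}

#' Tile a genome into fixed-width windows
#'
#' Produces consecutive, non-overlapping windows covering every chromosome;
#' the last window of a chromosome may be shorter than `width`. Used both
#' for the 50-kb spacing windows of panel design and the 3-Mb bins of the
#' heterozygosity analysis.
#'
#' @param genome A [genome_build()].
#' @param width Window width in bp (> 0).
#' @return Tibble with columns `chrom`, `start`, `end`, `window` (index
#'   within chromosome, 1-based).
#' @export
tile_windows <- function(genome, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    abort("`width` must be a single positive number.")
  }
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = width)
    tibble(
      chrom = genome$chrom[i],
      start = starts,
      end = pmin(starts + width, len),
      window = seq_along(starts)
    )
  })
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", attr(x, "build"), ": ", nrow(x),
      " chromosomes, ", format(sum(x$length), big.mark = ","), " bp\n",
      sep = "")
  NextMethod()
}
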