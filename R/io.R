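fmt_num <- function(x) {
  # integral values (positions, counts stored as double) print exactly;
  # fractional values at 6 significant digits
  ifelse(is.na(x), NA,
         ifelse(x == round(x) & abs(x) < 1e15,
                formatC(x, format = "d"),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

# write a tibble as TSV with numeric columns at 6 significant digits so
# writers are byte-deterministic
write_tsv_fixed <- function(tbl, path) {
  out <- tbl
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- fmt_num(out[[cc]])
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a genome build table
#'
#' TSV with columns `chrom`, `length`, `cen_start`, `cen_end` (bp).
#'
#' @param path File path.
#' @param build Build label. Default the file name.
#' @return A [genome_build()] tibble.
#' @export
read_genome <- function(path, build = basename(path)) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  genome_build(g, build = build)
}

#' @rdname read_genome
#' @param genome A `genome_build` to write.
#' @export
write_genome <- function(genome, path) {
  write_tsv_fixed(as_tibble(genome), path)
}

#' Read a BED file of intervals
#'
#' Plain browser-extensible-data format: tab-separated, no header, 0-based
#' half-open coordinates; columns beyond the third are kept as `name` and
#' `score` when present.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` (and `name`, `score`).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (ncol(b) < 3) abort(paste0("BED file ", path, " has fewer than 3 columns."))
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "name"
  if (ncol(b) >= 5) names(b)[5] <- "score"
  arrange(b, .data$chrom, .data$start)
}

#' @rdname read_bed
#' @export
read_exons <- read_bed

#' Write a panel as BED
#'
#' One single-base interval per SNP (`start = pos`, `end = pos + 1`), the
#' SNP identifier as name and its ranking-population MAF as score.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @export
write_panel_bed <- function(panel, path) {
  p <- as_tibble(panel)
  out <- tibble(chrom = p$chrom, start = p$pos, end = p$pos + 1,
                name = candidate_id(p), score = fmt_num(panel_maf(panel)))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_panel_bed
#' @param spacing Target spacing attribute to attach on read.
#' @export
read_panel_bed <- function(path, spacing = NULL) {
  b <- read_bed(path)
  panel <- tibble(chrom = b$chrom, pos = b$start,
                  id = if ("name" %in% names(b)) b$name else NA_character_,
                  maf = if ("score" %in% names(b)) as.numeric(b$score) else NA_real_)
  new_panel(arrange(panel, .data$chrom, .data$pos), spacing = spacing)
}

#' Read candidate SNPs from TSV or VCF
#'
#' The TSV dialect is the package's own candidate table (0-based `pos`,
#' `maf_<pop>` and `n_rr_/n_ra_/n_aa_<pop>` columns) and round-trips with
#' [write_candidates()]. VCF input (1-based positions, converted on read)
#' requires per-population INFO keys: `AF_<pop>` for allele frequencies and
#' `NRR_<pop>`, `NRA_<pop>`, `NAA_<pop>` for genotype counts, plus
#' optionally `GC`; key prefixes can be remapped through `info_keys`.
#'
#' @param path File path (`.vcf`/`.vcf.gz` parsed as VCF, anything else as
#'   TSV; override with `format`).
#' @param populations Population names expected. Default [design_config()]'s.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @param info_keys Named list of INFO key templates with `{pop}`
#'   placeholders.
#' @return Candidate tibble for [apply_site_filters()].
#' @export
read_candidates <- function(path,
                            populations = c("EAS", "EUR", "AFR", "AMR"),
                            format = c("auto", "tsv", "vcf"),
                            info_keys = list(maf = "AF_{pop}",
                                             n_rr = "NRR_{pop}",
                                             n_ra = "NRA_{pop}",
                                             n_aa = "NAA_{pop}",
                                             gc = "GC")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    cand <- readr::read_tsv(path, show_col_types = FALSE)
    return(arrange(as_tibble(cand), .data$chrom, .data$pos))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF candidates requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract_info_tidy(v)
  cand <- tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS) - 1,     # VCF is 1-based
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT
  )
  get_key <- function(template, pop) sub("{pop}", pop, template, fixed = TRUE)
  for (pop in populations) {
    for (fld in c("maf", "n_rr", "n_ra", "n_aa")) {
      key <- get_key(info_keys[[fld]], pop)
      if (!key %in% names(info)) {
        abort(paste0("VCF ", path, " is missing INFO key `", key, "`."))
      }
      col <- as.numeric(info[[key]])
      if (anyNA(col)) {
        bad <- which(is.na(col))[1]
        abort(paste0("missing INFO `", key, "` on record ", bad,
                     " (", cand$chrom[bad], ":", cand$pos[bad] + 1, ")."))
      }
      cand[[paste0(sub("n_", "n_", fld), "_", pop)]] <- col
    }
  }
  gc_key <- info_keys$gc
  if (!is.null(gc_key) && gc_key %in% names(info)) {
    cand$gc <- as.numeric(info[[gc_key]])
  }
  arrange(cand, .data$chrom, .data$pos)
}

#' @rdname read_candidates
#' @param candidates Candidate tibble to write (TSV dialect).
#' @export
write_candidates <- function(candidates, path) {
  write_tsv_fixed(as_tibble(candidates), path)
}

#' Read and write segment tables
#'
#' TSV with header `chrom`, `start`, `end` (0-based half-open) and any of
#' `n_sites`, `n_baf`, `logR`, `baf`, `depth`, `nA`, `nB`. Reading rejects
#' overlapping segments, and unknown chromosomes when a genome is supplied.
#'
#' @param path File path.
#' @param genome Optional [genome_build()] for chromosome validation.
#' @return Segment tibble.
#' @export
read_segments <- function(path, genome = NULL) {
  s <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (nrow(s) == 0) return(as_tibble(s))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(s))
  if (length(miss)) {
    abort(paste0("segment file ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  s <- arrange(as_tibble(s), .data$chrom, .data$start)
  ov <- s %>% group_by(.data$chrom) %>%
    summarise(bad = any(.data$start < lag(.data$end), na.rm = TRUE))
  if (any(ov$bad)) {
    abort(paste0("segment file ", path, ": overlapping segments on ",
                 paste(ov$chrom[ov$bad], collapse = ", ")))
  }
  if (!is.null(genome) && !all(s$chrom %in% genome$chrom)) {
    abort(paste0("segment file ", path, ": unknown chromosome ",
                 paste(setdiff(s$chrom, genome$chrom), collapse = ", ")))
  }
  s
}

#' @rdname read_segments
#' @param segments Segment tibble to write.
#' @export
write_segments <- function(segments, path) {
  if (inherits(segments, "ascn_fit")) segments <- segments$segments
  write_tsv_fixed(as_tibble(segments), path)
}

#' Read and write observation tables
#'
#' TSV with columns `chrom`, `pos` (0-based), `n_ref`, `n_alt`, `t_ref`,
#' `t_alt`, `normal_gt` — a simplified seqz-like per-SNP allele-depth
#' dialect.
#'
#' @param path File path.
#' @return Observation tibble.
#' @export
read_observations <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chrom", "pos", "n_ref", "n_alt", "t_ref", "t_alt", "normal_gt")
  miss <- setdiff(req, names(obs))
  if (length(miss)) {
    abort(paste0("observation file ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  arrange(as_tibble(obs), .data$chrom, .data$pos)
}

#' @rdname read_observations
#' @param obs Observation tibble to write.
#' @export
write_observations <- function(obs, path) {
  write_tsv_fixed(as_tibble(obs), path)
}

#' Write scar scores (and optional fit metadata) as JSON
#'
#' @param scores A `scar_scores` object.
#' @param path Output path.
#' @param fit Optional `ascn_fit` whose purity/ploidy/loglik are included.
#' @export
write_scores_json <- function(scores, path, fit = NULL) {
  x <- list(loh = scores$loh, tai = scores$tai, lst = scores$lst,
            hrd = scores$hrd, status = scores$status,
            cutoff = scores$cutoff)
  if (!is.null(fit)) {
    x$purity <- fit$purity
    x$ploidy <- fit$ploidy
    x$loglik <- fit$loglik
    x$identifiable <- fit$identifiable
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' A versioned YAML file (`schema: 1`) holding file paths and module
#' parameter blocks. Unknown top-level keys raise a warning, never a
#' silent drop.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema", "genome", "candidates", "exons", "panel",
             "observations", "segments", "out_dir", "seed", "design",
             "fit", "scars", "simulate", "experiments", "log_level")
  if (is.null(cfg$schema)) {
    abort(paste0("config ", path, " is missing the `schema` key."))
  }
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    warn(paste0("config ", path, ": unknown key(s) ignored: ",
                paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}
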