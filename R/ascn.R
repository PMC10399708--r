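#' Expected B-allele fraction under the purity mixture model
#'
#' At a germline-heterozygous SNP inside a tumor segment with allele-specific
#' copies (nA, nB), a fraction `purity` of cells carry nB copies of the B
#' allele out of nA+nB, and the remaining normal cells carry 1 of 2:
#' \deqn{b = (p\,nB + (1-p)) / (p(nA+nB) + 2(1-p)).}
#'
#' @param purity Tumor purity in (0, 1].
#' @param nA,nB Integer allele-specific copy numbers, nA >= nB >= 0.
#' @param folded Return `min(b, 1-b)` (the orientation-free value used
#'   throughout the fit). Default `TRUE`.
#' @return Numeric vector of expected (folded) B-allele fractions.
#' @export
expected_baf <- function(purity, nA, nB, folded = TRUE) {
  den <- purity * (nA + nB) + 2 * (1 - purity)
  b <- ifelse(den > 1e-12, (purity * nB + (1 - purity)) / den, 0.5)
  if (folded) pmin(b, 1 - b) else b
}

#' Expected tumor/normal depth ratio under the purity-ploidy mixture model
#'
#' \deqn{R = (p(nA+nB) + 2(1-p)) / (p\psi + 2(1-p))}
#' where \eqn{\psi} is the sample ploidy (genome-wide length-weighted mean
#' total copy number). The expected logR of a segment is `log2(R)`.
#'
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Sample ploidy.
#' @param nA,nB Allele-specific copy numbers.
#' @return Numeric vector of expected depth ratios.
#' @export
expected_depth_ratio <- function(purity, ploidy, nA, nB) {
  (purity * (nA + nB) + 2 * (1 - purity)) /
    (purity * ploidy + 2 * (1 - purity))
}

# Mean of the folded statistic 0.5 - |V - 0.5| when V ~ N(b, sd): binomial
# sampling noise pulls the folded BAF of balanced segments below 0.5, and
# the fit must predict the same quantity it is compared against.
folded_baf_mean <- function(b, sd) {
  mu <- abs(b - 0.5)
  out <- 0.5 - mu
  pos <- sd > 1e-9
  if (any(pos)) {
    m <- mu[pos]; s <- sd[pos]
    e_abs <- s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) +
      m * (1 - 2 * pnorm(-m / s))
    out[pos] <- 0.5 - e_abs
  }
  out
}

#' Per-site logR and folded BAF signals
#'
#' Converts raw tumor/normal allele counts into the two signals that drive
#' copy-number inference: `logR`, the log2 tumor/normal depth ratio after
#' library-size normalisation (total tumor reads scaled to total normal
#' reads, so the genome-average ratio is 1 and the absolute ploidy stays
#' identifiable), and the folded B-allele fraction `min(VAF, 1-VAF)`,
#' defined only at germline-heterozygous sites. Sites below `min_depth` in
#' either sample are dropped; sites with zero normal depth are dropped with
#' a warning rather than dividing by zero.
#'
#' @param obs Observation tibble (see [simulate_observations()] or
#'   [read_observations()]).
#' @param min_depth Minimum depth required in each sample. Default 30.
#' @return Tibble of class `site_signal`: `chrom`, `pos`, `logR`, `baf`
#'   (`NA` at non-heterozygous sites), `depth` (tumor depth), `het`.
#' @export
compute_signals <- function(obs, min_depth = 30) {
  obs <- arrange(as_tibble(obs), .data$chrom, .data$pos)
  nd <- obs$n_ref + obs$n_alt
  td <- obs$t_ref + obs$t_alt
  zero <- nd == 0 & td >= min_depth
  if (any(zero) && min_depth == 0) {
    warn(paste0(sum(zero), " site(s) with zero normal depth dropped."))
  }
  keep <- nd >= pmax(min_depth, 1) & td >= min_depth
  obs <- obs[keep, ]; nd <- nd[keep]; td <- td[keep]
  if (nrow(obs) == 0) abort("no sites pass the depth filter.")
  norm <- log2(sum(td) / sum(nd))
  logr <- log2(td / nd) - norm
  het <- obs$normal_gt == "het"
  vaf <- ifelse(td > 0, obs$t_alt / td, NA_real_)
  baf <- ifelse(het, pmin(vaf, 1 - vaf), NA_real_)
  out <- tibble(chrom = obs$chrom, pos = obs$pos, logR = logr, baf = baf,
                depth = td, het = het)
  structure(out, class = c("site_signal", class(out)))
}

# Best split of x (and optional second signal b with NAs) by combined
# sum-of-squares gain; returns list(gain, index) for the split after `index`.
best_split <- function(x, b, s2x, s2b, min_sites) {
  n <- length(x)
  if (n < 2 * min_sites) return(list(gain = -Inf, index = NA_integer_))
  i <- seq(min_sites, n - min_sites)
  cx <- cumsum(x)
  gain_x <- cx[i]^2 / i + (cx[n] - cx[i])^2 / (n - i) - cx[n]^2 / n
  gain <- gain_x / s2x
  if (!is.null(b)) {
    ok <- !is.na(b)
    if (any(ok)) {
      cb <- cumsum(ifelse(ok, b, 0))
      cn <- cumsum(ok)
      nl <- cn[i]; nr <- cn[n] - cn[i]
      gb <- ifelse(nl > 0, cb[i]^2 / nl, 0) +
        ifelse(nr > 0, (cb[n] - cb[i])^2 / nr, 0) -
        cb[n]^2 / max(cn[n], 1)
      gain <- gain + gb / s2b
    }
  }
  k <- which.max(gain)
  list(gain = gain[k], index = i[k])
}

robust_site_sd <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 3) return(NA_real_)
  stats::mad(diff(v)) / sqrt(2)
}

#' Segment logR/BAF signals by recursive binary segmentation
#'
#' Splits each chromosome recursively at the position maximising the joint
#' sum-of-squares gain of the logR and folded-BAF signals (each standardised
#' by a robust noise estimate from successive differences), accepting a
#' split only when the gain exceeds a BIC-style penalty. Breakpoints never
#' cross chromosome boundaries and every site belongs to exactly one
#' segment. Segment intervals are contiguous within the covered extent of a
#' chromosome (boundaries at midpoints between flanking sites).
#'
#' @param signals A [compute_signals()] tibble.
#' @param genome A [genome_build()].
#' @param penalty Split-acceptance penalty on the standardised gain;
#'   `NULL` (default) uses `10 * log(n)` with n the sites on the
#'   chromosome.
#' @param min_sites Minimum sites per segment. Default 10.
#' @return Segment tibble: `chrom`, `start`, `end`, `n_sites`, `n_baf`,
#'   `logR`, `baf`, `depth`, `sd_logR`, `sd_baf`.
#' @export
segment_sites <- function(signals, genome, penalty = NULL, min_sites = 10) {
  signals <- arrange(as_tibble(signals), .data$chrom, .data$pos)
  out <- list()
  for (ch in unique(signals$chrom)) {
    s <- signals[signals$chrom == ch, ]
    n <- nrow(s)
    pen <- if (is.null(penalty)) 10 * log(max(n, 2)) else penalty
    s2x <- max(robust_site_sd(s$logR), 0.01, na.rm = TRUE)^2
    s2b <- max(robust_site_sd(s$baf), 0.005, na.rm = TRUE)^2
    breaks <- integer(0)
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      rg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lo <- rg[1]; hi <- rg[2]
      sp <- best_split(s$logR[lo:hi], s$baf[lo:hi], s2x, s2b, min_sites)
      if (is.finite(sp$gain) && sp$gain > pen) {
        cut <- lo + sp$index - 1L
        breaks <- c(breaks, cut)
        stack <- c(stack, list(c(lo, cut)), list(c(cut + 1L, hi)))
      }
    }
    bounds <- sort(unique(c(0L, breaks, n)))
    seg_first <- head(bounds, -1) + 1L
    seg_last <- tail(bounds, -1)
    # contiguous intervals: cut at midpoints between adjacent sites
    cutpos <- if (length(seg_last) > 1) {
      floor((s$pos[seg_last[-length(seg_last)]] +
               s$pos[seg_first[-1]]) / 2)
    } else numeric(0)
    starts <- c(s$pos[1], cutpos)
    ends <- c(cutpos, s$pos[n] + 1)
    out[[length(out) + 1]] <- purrr::map_dfr(seq_along(seg_first), function(k) {
      ix <- seg_first[k]:seg_last[k]
      bafv <- s$baf[ix]
      nb <- sum(!is.na(bafv))
      tibble(
        chrom = ch, start = starts[k], end = ends[k],
        n_sites = length(ix), n_baf = nb,
        logR = mean(s$logR[ix]),
        baf = if (nb > 0) mean(bafv, na.rm = TRUE) else NA_real_,
        depth = mean(s$depth[ix]),
        sd_logR = if (length(ix) > 1) sd(s$logR[ix]) else NA_real_,
        sd_baf = if (nb > 1) sd(bafv, na.rm = TRUE) else NA_real_
      )
    })
  }
  bind_rows(out)
}

# 25 integer states (nA >= nB >= 0, nA+nB <= max_total)
cn_states <- function(max_total = 8) {
  t <- unlist(lapply(0:max_total, function(k) rep(k, floor(k / 2) + 1)))
  nb <- unlist(lapply(0:max_total, function(k) 0:floor(k / 2)))
  tibble(nA = t - nb, nB = nb, total = t)
}

seg_fit_weights <- function(segments) {
  n <- segments$n_sites
  nb <- segments$n_baf
  sdR <- if ("sd_logR" %in% names(segments)) segments$sd_logR else NA_real_
  sdB <- if ("sd_baf" %in% names(segments)) segments$sd_baf else NA_real_
  # missing scatter columns (e.g. exact model-generated means) default to
  # the floor: tight weights, so exact solutions dominate
  sdR <- pmax(ifelse(is.na(sdR), 0.02, sdR), 0.02)
  sdB <- pmax(ifelse(is.na(sdB), 0.005, sdB), 0.005)
  list(
    wR = n / sdR^2,
    wB = ifelse(nb > 0, nb / sdB^2, 0),
    depth = if ("depth" %in% names(segments)) segments$depth else rep(Inf, nrow(segments))
  )
}

#' Fit tumor purity and ploidy by exhaustive grid search
#'
#' Maximises a Gaussian log-likelihood of the observed segment means
#' (logR and folded BAF) around their model expectations under the best
#' integer allele-specific copy-number state per segment (total copies
#' <= `max_total_cn`), over an exhaustive purity x ploidy grid. Segment
#' terms are weighted by supporting-site counts and within-segment scatter.
#' The folded-BAF expectation includes the fold-bias of binomial noise at
#' balanced states (see [expected_baf()]).
#'
#' The purity-ploidy mixture model has a well-known ridge of near-
#' equivalent solutions (ploidy doubling, and more generally adding one
#' copy of each allele per tumor cell at a compensating purity); such
#' solutions differ only by finite-sample noise. Grid solutions within
#' `tol` log-likelihood units of the optimum that disagree are therefore
#' treated as ties: the solution with the lowest ploidy is returned and
#' the identifiability flag is set.
#'
#' @param segments Segment tibble from [segment_sites()] (columns `logR`,
#'   `baf`, `n_sites`, `n_baf`; optional `depth`, `sd_logR`, `sd_baf`).
#' @param purity_grid,ploidy_grid Grids searched exhaustively. Defaults
#'   0.10-1.00 by 0.01 and 1.0-7.0 by 0.1.
#' @param max_total_cn Largest total copy number considered. Default 8.
#' @param tol Log-likelihood tolerance defining near-ties; `NULL`
#'   (default) scales with the fit size as `max(3, 6 * sqrt(n_terms))`,
#'   since the log-likelihood gap between degenerate solutions grows with
#'   the square root of the number of segment terms while the gap to
#'   genuinely different solutions grows linearly.
#' @return List with `purity`, `ploidy`, `loglik`, `identifiable` (logical;
#'   `FALSE` when degenerate solutions were found), and `surface` (the
#'   log-likelihood matrix, purities in rows).
#' @export
fit_purity_ploidy <- function(segments,
                              purity_grid = seq(0.10, 1.00, by = 0.01),
                              ploidy_grid = seq(1.0, 7.0, by = 0.1),
                              max_total_cn = 8, tol = NULL) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0) abort("no segments to fit.")
  has_baf <- !is.na(segments$baf) & segments$n_baf > 0
  if (!any(has_baf)) {
    abort("unidentifiable: no segments with BAF support.")
  }
  st <- cn_states(max_total_cn)
  w <- seg_fit_weights(segments)
  if (is.null(tol)) {
    tol <- max(3, 6 * sqrt(nrow(segments) + sum(has_baf)))
  }
  S <- nrow(segments)
  K <- nrow(st)
  L <- segments$logR
  Bobs <- ifelse(is.na(segments$baf), 0, segments$baf)
  wB <- ifelse(has_baf, w$wB, 0)
  nP <- length(purity_grid)
  nQ <- length(ploidy_grid)
  cost <- matrix(NA_real_, nP, nQ,
                 dimnames = list(purity = purity_grid, ploidy = ploidy_grid))
  dvec <- ifelse(is.finite(w$depth) & w$depth > 0, w$depth, Inf)

  # purity-specific model pieces shared by every ploidy
  p_context <- function(p) {
    num <- p * st$total + 2 * (1 - p)
    A <- log2(pmax(num, 1e-9))                     # state depth term
    braw <- ifelse(num > 1e-12, (p * st$nB + (1 - p)) / num, 0.5)
    # fold-bias-corrected expected folded BAF: K x S
    sdmat <- outer(sqrt(pmax(braw * (1 - braw), 0)),
                   ifelse(is.finite(dvec), 1 / sqrt(dvec), 0))
    EB <- matrix(folded_baf_mean(rep(braw, S), as.vector(sdmat)), K, S)
    Cmat <- sweep((EB - matrix(Bobs, K, S, byrow = TRUE))^2, 2, wB, `*`)
    D <- matrix(A, K, S) - matrix(L, K, S, byrow = TRUE)
    list(p = p, Cmat = Cmat, D = D)
  }
  cost_at <- function(ctx, psi) {
    Bq <- log2(pmax(ctx$p * psi + 2 * (1 - ctx$p), 1e-9))
    M <- sweep((ctx$D - Bq)^2, 2, w$wR, `*`) + ctx$Cmat
    best <- M[1, ]
    for (k in 2:K) best <- pmin(best, M[k, ])
    sum(best)
  }

  contexts <- vector("list", nP)
  for (ip in seq_len(nP)) {
    ctx <- p_context(purity_grid[ip])
    contexts[[ip]] <- ctx
    # expand over the ploidy grid in one block
    Bq <- log2(pmax(ctx$p * ploidy_grid + 2 * (1 - ctx$p), 1e-9))
    Dq <- ctx$D[, rep(seq_len(S), times = nQ), drop = FALSE] -
      matrix(rep(Bq, each = S), K, S * nQ, byrow = TRUE)
    M <- sweep(Dq^2, 2, rep(w$wR, times = nQ), `*`) +
      ctx$Cmat[, rep(seq_len(S), times = nQ), drop = FALSE]
    best <- M[1, ]
    for (k in 2:K) best <- pmin(best, M[k, ])
    cost[ip, ] <- colSums(matrix(best, S, nQ))
  }

  # Sub-grid polish: the truth ploidy rarely sits exactly on the 0.1 grid,
  # and the doubling degeneracy makes relative quantisation error decide
  # between psi and 2*psi. Refine psi within each column's half-step at the
  # column's best purity, then compare columns.
  half <- if (nQ > 1) diff(ploidy_grid)[1] / 2 else 0.05
  ref_cost <- ref_psi <- ref_p <- numeric(nQ)
  for (jq in seq_len(nQ)) {
    ip <- which.min(cost[, jq])
    ctx <- contexts[[ip]]
    o <- stats::optimize(function(ps) cost_at(ctx, ps),
                         interval = c(ploidy_grid[jq] - half,
                                      ploidy_grid[jq] + half))
    ref_cost[jq] <- min(o$objective, cost[ip, jq])
    ref_psi[jq] <- if (o$objective <= cost[ip, jq]) o$minimum else
      ploidy_grid[jq]
    ref_p[jq] <- purity_grid[ip]
  }

  ll <- -0.5 * cost
  ref_ll <- -0.5 * ref_cost
  top <- max(ref_ll)
  cand <- which(ref_ll >= top - tol)
  disagree <- (max(ref_psi[cand]) - min(ref_psi[cand]) > 0.25) ||
    (max(ref_p[cand]) - min(ref_p[cand]) > 0.05)
  # lowest ploidy among near-ties; then best likelihood; then highest purity
  ord <- cand[order(ref_psi[cand], -ref_ll[cand], -ref_p[cand])]
  pick <- ord[1]
  list(
    purity = ref_p[pick],
    ploidy = round(ref_psi[pick], 4),
    loglik = ref_ll[pick],
    identifiable = !disagree,
    surface = ll
  )
}

#' Assign integer allele-specific copy numbers to segments
#'
#' Given fitted purity and ploidy, each segment receives the (nA, nB) state
#' (nA >= nB, total <= `max_total_cn`) minimising the weighted squared
#' residual of its observed (logR, folded BAF) against the model
#' expectation. Segments without BAF support are matched on logR only and
#' take the nearest balanced split (nB = floor(total/2)).
#'
#' @param segments Segment tibble.
#' @param purity,ploidy Fitted values.
#' @param max_total_cn Largest total copy number considered. Default 8.
#' @return The segment tibble with integer `nA` and `nB` columns.
#' @export
assign_ascn <- function(segments, purity, ploidy, max_total_cn = 8) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0) {
    return(mutate(segments, nA = integer(0), nB = integer(0)))
  }
  st <- cn_states(max_total_cn)
  w <- seg_fit_weights(segments)
  p <- purity
  num <- p * st$total + 2 * (1 - p)
  ER <- log2(pmax(num, 1e-9)) - log2(p * ploidy + 2 * (1 - p))
  braw <- ifelse(num > 1e-12, (p * st$nB + (1 - p)) / num, 0.5)
  nA <- nB <- integer(nrow(segments))
  has_baf <- !is.na(segments$baf) &
    (if ("n_baf" %in% names(segments)) segments$n_baf > 0 else TRUE)
  for (i in seq_len(nrow(segments))) {
    rR <- w$wR[i] * (ER - segments$logR[i])^2
    if (has_baf[i]) {
      d <- w$depth[i]
      sdv <- if (is.finite(d) && d > 0) sqrt(pmax(braw * (1 - braw), 0) / d) else 0
      EB <- folded_baf_mean(braw, sdv)
      res <- rR + w$wB[i] * (EB - segments$baf[i])^2
      k <- which.min(res)
      nA[i] <- st$nA[k]; nB[i] <- st$nB[k]
    } else {
      # logR only: pick total copy number, then the balanced split
      tot_res <- vapply(unique(st$total), function(t) {
        min(rR[st$total == t])
      }, numeric(1))
      t_best <- unique(st$total)[which.min(tot_res)]
      nB[i] <- floor(t_best / 2); nA[i] <- t_best - nB[i]
    }
  }
  mutate(segments, nA = as.integer(nA), nB = as.integer(nB))
}

#' Full allele-specific copy-number inference from observations
#'
#' Convenience pipeline: [compute_signals()], [segment_sites()],
#' [fit_purity_ploidy()] and [assign_ascn()] in sequence.
#'
#' @param obs Observation tibble.
#' @param genome A [genome_build()].
#' @param min_depth Passed to [compute_signals()].
#' @param penalty,min_sites Passed to [segment_sites()].
#' @param ... Passed to [fit_purity_ploidy()].
#' @return A list of class `ascn_fit` with `purity`, `ploidy`, `loglik`,
#'   `identifiable`, `segments` (with assigned `nA`, `nB`), `surface` and
#'   `n_sites`.
#' @export
fit_ascn <- function(obs, genome, min_depth = 30, penalty = NULL,
                     min_sites = 10, ...) {
  sig <- compute_signals(obs, min_depth = min_depth)
  segs <- segment_sites(sig, genome, penalty = penalty,
                        min_sites = min_sites)
  fit <- fit_purity_ploidy(segs, ...)
  segs <- assign_ascn(segs, fit$purity, fit$ploidy)
  structure(
    list(purity = fit$purity, ploidy = fit$ploidy, loglik = fit$loglik,
         identifiable = fit$identifiable, segments = segs,
         surface = fit$surface, n_sites = nrow(sig)),
    class = "ascn_fit"
  )
}

#' @export
print.ascn_fit <- function(x, ...) {
  cat("<ascn_fit> purity ", x$purity, ", ploidy ", x$ploidy,
      ", ", nrow(x$segments), " segments over ", x$n_sites, " sites",
      if (!x$identifiable) " [degenerate fit: lowest-ploidy solution]",
      "\n", sep = "")
  invisible(x)
}
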