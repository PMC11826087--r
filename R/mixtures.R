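#' Enumerate candidate k-population mixtures
#'
#' All combinations of `k` pools of one origin, in deterministic
#' lexicographic order (panel order within each combination).
#'
#' @param panel pool panel data.frame.
#' @param origin origin level to draw from (`"native"` or `"invasive"`).
#' @param k mixture size (default 5 source populations per mixture).
#' @return character matrix with `k` rows, one column per combination.
#' @examples
#' panel <- data.frame(pool_id = paste0("p", 1:6), origin = "native",
#'                     n_maternal = 20L)
#' ncol(enumerateMixtures(panel, "native", k = 5))   # choose(6, 5) = 6
#' @export
enumerateMixtures <- function(panel, origin, k = 5L) {
  panel <- validatePanel(panel)
  ids <- panel$pool_id[panel$origin == origin]
  if (length(ids) < k)
    stop("only ", length(ids), " pools of origin '", origin,
         "' but k = ", k)
  utils::combn(ids, k)
}

#' Mean pairwise FST of a mixture
#'
#' The predicted diversity score of a candidate mixture: the arithmetic mean
#' of the `choose(k, 2)` pairwise FST entries among its members.
#'
#' @param members character vector of pool ids (the mixture).
#' @param fst a [PoolDist-class] of kind `"fst"`.
#' @return numeric score.
#' @export
scoreMixture <- function(members, fst) {
  v <- distValues(fst)
  bad <- setdiff(members, rownames(v))
  if (length(bad))
    stop("members absent from FST matrix: ", paste(bad, collapse = ", "))
  sub <- v[members, members]
  lt <- lower.tri(sub)
  if (anyNA(sub[lt])) {
    idx <- which(lt & is.na(sub), arr.ind = TRUE)
    stop("missing pairwise FST for pair(s): ",
         paste(members[idx[, 2]], members[idx[, 1]],
               sep = "-", collapse = ", "))
  }
  mean(sub[lt])
}

#' Score every candidate mixture
#'
#' @param combos character matrix from [enumerateMixtures()].
#' @param fst a [PoolDist-class] of kind `"fst"`.
#' @return data.frame with `mixture_id` (`mix0001`, ...), `members`
#'   (slash-separated), `predicted_score`; rows in enumeration order.
#' @export
scoreAllMixtures <- function(combos, fst) {
  scores <- apply(combos, 2, scoreMixture, fst = fst)
  data.frame(
    mixture_id = sprintf("mix%04d", seq_len(ncol(combos))),
    members = apply(combos, 2, paste, collapse = "/"),
    predicted_score = scores,
    row.names = NULL)
}

#' Stratified random selection of mixtures along the diversity gradient
#'
#' Divides the observed score range into `n_strata` equal-width bins
#' (default: one per selection) and draws one mixture uniformly at random per
#' bin, sweeping bins from lowest to highest score, so the selections cover
#' the whole predicted-diversity gradient.  An empty (or exhausted) bin is
#' backfilled from the nearest non-empty bin.  With a degenerate score range
#' (all scores equal) a simple random sample is drawn with a warning.
#' Deterministic given `seed`.
#'
#' An optional `max_reuse` caps how many selected mixtures may share any one
#' source population; candidates violating the cap are skipped during the
#' draw.
#'
#' @param scored data.frame from [scoreAllMixtures()].
#' @param m number of mixtures to select (default 15).
#' @param n_strata number of equal-width bins (default `m`).
#' @param seed integer seed.
#' @param max_reuse maximum number of selected mixtures any single pool may
#'   appear in (default `Inf`, i.e. unrestricted).
#' @return data.frame of `m` rows, columns of `scored` plus `stratum`,
#'   sorted by `predicted_score`.
#' @export
stratifiedSelect <- function(scored, m = 15L, n_strata = m, seed = 1L,
                             max_reuse = Inf) {
  if (m < 1) stop("m must be >= 1")
  if (nrow(scored) < m)
    stop("only ", nrow(scored), " candidates for m = ", m)
  s <- scored$predicted_score
  set.seed(seed)
  rng <- range(s)
  if (diff(rng) == 0) {
    warning("degenerate score range: falling back to simple random sample")
    pick <- sample.int(nrow(scored), m)
    out <- scored[pick, , drop = FALSE]
    out$stratum <- NA_integer_
    return(out[order(out$predicted_score), , drop = FALSE])
  }
  breaks <- seq(rng[1], rng[2], length.out = n_strata + 1)
  bin <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  taken <- logical(nrow(scored))
  use_count <- new.env(parent = emptyenv())
  okReuse <- function(i) {
    if (!is.finite(max_reuse)) return(TRUE)
    mem <- strsplit(scored$members[i], "/", fixed = TRUE)[[1]]
    all(vapply(mem, function(p)
      (if (is.null(use_count[[p]])) 0L else use_count[[p]]) < max_reuse,
      logical(1)))
  }
  bumpReuse <- function(i) {
    if (!is.finite(max_reuse)) return(invisible())
    mem <- strsplit(scored$members[i], "/", fixed = TRUE)[[1]]
    for (p in mem)
      use_count[[p]] <- (if (is.null(use_count[[p]])) 0L
                         else use_count[[p]]) + 1L
  }
  # sweep: target bins cycle low -> high until m draws are made
  target_bins <- rep_len(seq_len(n_strata), m)
  picks <- integer(0)
  for (b in target_bins) {
    cand <- which(bin == b & !taken)
    cand <- cand[vapply(cand, okReuse, logical(1))]
    if (!length(cand)) {
      # fallback: nearest non-empty bin not yet exhausted
      for (d in seq_len(n_strata)) {
        for (bb in unique(c(b - d, b + d))) {
          if (bb < 1 || bb > n_strata) next
          cand <- which(bin == bb & !taken)
          cand <- cand[vapply(cand, okReuse, logical(1))]
          if (length(cand)) break
        }
        if (length(cand)) break
      }
    }
    if (!length(cand))
      stop("candidate set exhausted (max_reuse too restrictive?)")
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    taken[pick] <- TRUE
    bumpReuse(pick)
    picks <- c(picks, pick)
  }
  out <- scored[picks, , drop = FALSE]
  out$stratum <- bin[picks]
  out[order(out$predicted_score), , drop = FALSE]
}

#' Realized heterozygosity of a mixture
#'
#' The diversity actually attained by a de-novo population: member pools'
#' read counts are summed element-wise and the unbiased per-locus
#' heterozygosity of the summed column is averaged across loci (delegates to
#' [totalHe()]).
#'
#' @param members character vector of pool ids.
#' @param x a [PoolCounts-class] object.
#' @return realized He in \[0, 1\].
#' @export
mixtureHe <- function(members, x) {
  bad <- setdiff(members, colnames(x))
  if (length(bad))
    stop("mixture members absent from counts table: ",
         paste(bad, collapse = ", "))
  totalHe(x, members)
}

#' Assemble the seed manifest of a mixture
#'
#' Every selected mixture is realised as a physical seed sample: equal seed
#' numbers from each member population, themselves drawn in equal proportions
#' from that population's maternal plants.  The default (5 populations x 20
#' seeds) gives the 100-seed samples used per experimental unit.  When
#' `seeds_per_population` is not a multiple of the maternal-plant count, the
#' remainder is assigned one extra seed per maternal plant, lowest index
#' first (deterministic).
#'
#' @param members character vector of pool ids.
#' @param panel pool panel (for `n_maternal`).
#' @param seeds_per_population seeds contributed by each member (default 20).
#' @return list with `total_seeds`, `per_population` (named vector) and
#'   `allocation` (data.frame pool_id, maternal_plant, n_seeds).
#' @export
assembleSeedManifest <- function(members, panel, seeds_per_population = 20L) {
  panel <- validatePanel(panel)
  idx <- match(members, panel$pool_id)
  if (anyNA(idx))
    stop("members absent from panel: ",
         paste(members[is.na(idx)], collapse = ", "))
  alloc <- do.call(rbind, lapply(seq_along(members), function(i) {
    nm <- panel$n_maternal[idx[i]]
    base <- seeds_per_population %/% nm
    extra <- seeds_per_population %% nm
    data.frame(pool_id = members[i], maternal_plant = seq_len(nm),
               n_seeds = base + as.integer(seq_len(nm) <= extra))
  }))
  per_pop <- stats::setNames(rep(as.integer(seeds_per_population),
                                 length(members)), members)
  list(total_seeds = as.integer(length(members) * seeds_per_population),
       per_population = per_pop, allocation = alloc)
}

#' Expand the full experimental design
#'
#' Full factorial crossing of mixtures (per origin) x microsite-availability
#' levels x replicates, one row per experimental unit, with a seeded random
#' placement order recorded as a column.  The microsite treatment is encoded
#' by the number of matrix-grass (Festuca) plants: 0 = high availability,
#' 5 = medium, 10 = low.
#'
#' @param mixtures data.frame with columns `mixture_id`, `origin` (and
#'   optionally `realized_He`, carried through).
#' @param msa_levels named integer vector of Festuca plants per level
#'   (default `c(high = 0, medium = 5, low = 10)`).
#' @param n_replicates replicates per cell (default 3).
#' @param seed seed for the placement permutation.
#' @return data.frame (the design table) with `unit_id`, `mixture_id`,
#'   `origin`, `msa`, `n_festuca`, `replicate`, `placement_order`.
#' @examples
#' mx <- data.frame(mixture_id = paste0("m", 1:15),
#'                  origin = rep(c("native", "invasive"), length.out = 15))
#' # 15 mixtures x 3 levels x 3 replicates = 135 units
#' nrow(expandDesign(mx))
#' @export
expandDesign <- function(mixtures,
                         msa_levels = c(high = 0L, medium = 5L, low = 10L),
                         n_replicates = 3L, seed = 1L) {
  stopifnot(all(c("mixture_id", "origin") %in% colnames(mixtures)))
  if (anyDuplicated(mixtures$mixture_id))
    stop("mixture_ids must be unique")
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      msa = names(msa_levels),
                      mixture_id = mixtures$mixture_id,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("mixture_id", "msa", "replicate")]
  grid <- merge(grid, mixtures, by = "mixture_id", sort = FALSE)
  grid$n_festuca <- as.integer(msa_levels[grid$msa])
  grid$msa <- factor(grid$msa, levels = names(msa_levels))
  grid <- grid[order(grid$mixture_id, grid$msa, grid$replicate), ,
               drop = FALSE]
  grid$unit_id <- sprintf("unit%03d", seq_len(nrow(grid)))
  set.seed(seed)
  grid$placement_order <- sample.int(nrow(grid))
  rownames(grid) <- NULL
  first <- c("unit_id", "mixture_id", "origin", "msa", "n_festuca",
             "replicate", "placement_order")
  grid[, c(first, setdiff(colnames(grid), first)), drop = FALSE]
}

#' Design mixtures end-to-end
#'
#' Convenience chain: enumerate candidates per origin, score them on the
#' pairwise-FST matrix, select a stratified sample of `m` per origin, and
#' attach each selection's realized He from the read counts.
#'
#' @param x a filtered [PoolCounts-class] object.
#' @param k mixture size (default 5).
#' @param m selections per origin (default 15).
#' @param seed integer seed (per-origin streams are derived from it).
#' @param max_reuse see [stratifiedSelect()].
#' @return data.frame of `2 * m` mixtures with `mixture_id`, `origin`,
#'   `members`, `predicted_score`, `realized_He`, `stratum`.
#' @export
designMixtures <- function(x, k = 5L, m = 15L, seed = 1L, max_reuse = Inf) {
  panel <- poolPanel(x)
  fst <- fstMatrix(x, by_origin = TRUE)
  out <- lapply(sort(unique(panel$origin)), function(og) {
    combos <- enumerateMixtures(panel, og, k = k)
    scored <- scoreAllMixtures(combos, fst)
    sel <- stratifiedSelect(scored, m = m, seed = seed, max_reuse = max_reuse)
    sel$origin <- og
    sel$realized_He <- vapply(strsplit(sel$members, "/", fixed = TRUE),
                              mixtureHe, numeric(1), x = x)
    sel$mixture_id <- sprintf("%s%02d", substr(og, 1, 3), seq_len(nrow(sel)))
    sel
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("mixture_id", "origin", "members", "predicted_score",
          "realized_He", "stratum")]
}
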