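#' Category-wise forward selection of environmental predictors
#'
#' Starting from the geography-only model, forward selection runs
#' independently within each variable category (e.g. Water, Energy, Soil):
#' at each step the variable giving the largest gain in deviance explained
#' is added, and selection stops when no variable gains at least
#' `threshold_pct` percentage points. The union of per-category selections
#' is the candidate set. By default the within-category model grows as
#' variables are accepted (`cumulative = TRUE`); `cumulative = FALSE`
#' scores every candidate against the geography-only base instead.
#'
#' @param pairs A [build_pair_table()] result with environment columns.
#' @param env_meta data.frame `variable`, `category`; default taken from
#'   the pair table.
#' @param threshold_pct Minimum gain in percentage points (default 1).
#' @param cumulative Grow the within-category model (default) or score
#'   against the base model only.
#' @return List of class `selection_trace`: `selected` (character),
#'   `base_de` (geography-only deviance explained), `trace` (data.frame
#'   `step`, `category`, `variable`, `deviance_explained`, `gain`,
#'   `accepted`).
#' @export
forward_select <- function(pairs, env_meta = attr(pairs, "env_meta"),
                           threshold_pct = 1, cumulative = TRUE) {
  if (is.null(env_meta)) stop("pair table has no environment metadata")
  base <- fit_gdm(pairs)
  base_de <- deviance_explained(base)
  trace <- list()
  selected <- character(0)
  step <- 0L
  for (cat in unique(env_meta$category)) {
    cat_vars <- env_meta$variable[env_meta$category == cat]
    current <- character(0)
    current_de <- base_de
    repeat {
      cand <- setdiff(cat_vars, current)
      if (!length(cand)) break
      des <- vapply(cand, function(v) {
        in_fit <- if (cumulative) c(current, v) else v
        deviance_explained(fit_gdm(pairs, in_fit))
      }, numeric(1))
      bi <- which.max(des)
      gain <- des[bi] - current_de
      step <- step + 1L
      accept <- gain >= threshold_pct
      trace[[step]] <- data.frame(step = step, category = cat,
                                  variable = cand[bi],
                                  deviance_explained = des[bi],
                                  gain = gain, accepted = accept,
                                  stringsAsFactors = FALSE)
      if (!accept) break
      current <- c(current, cand[bi])
      if (cumulative) current_de <- des[bi]
    }
    selected <- c(selected, current)
  }
  structure(list(selected = selected, base_de = base_de,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame()),
            class = "selection_trace")
}

# Replace a variable's locality values in a pair table according to a
# permutation of localities (all samples of a locality move together).
.permute_env_var <- function(pairs, variable, perm_map) {
  pairs[[paste0("x1_", variable)]] <-
    perm_map[pairs$loc1, variable]
  pairs[[paste0("x2_", variable)]] <-
    perm_map[pairs$loc2, variable]
  pairs
}

# Current locality -> variable value matrix implied by a pair table.
.pair_env_matrix <- function(pairs, variables) {
  locs <- unique(c(pairs$loc1, pairs$loc2))
  m <- matrix(NA_real_, length(locs), length(variables),
              dimnames = list(locs, variables))
  for (v in variables) {
    x1 <- pairs[[paste0("x1_", v)]]
    x2 <- pairs[[paste0("x2_", v)]]
    m[, v] <- c(x1, x2)[match(locs, c(pairs$loc1, pairs$loc2))]
  }
  m
}

#' Permutation importance of one predictor in a fitted GDM
#'
#' Each replicate permutes the variable's values across localities (all
#' samples of a locality move together; geography and the other predictors
#' stay fixed), refits the model and records the permuted deviance
#' explained. Importance is the mean percent drop,
#' 100 * (DE_full - mean DE_perm) / DE_full, and
#' p = (1 + #\{DE_perm >= DE_full\}) / (n_perm + 1).
#'
#' @param pairs Site-pair table used to fit `model`.
#' @param model A [fit_gdm()] model containing `variable`.
#' @param variable Predictor name to permute.
#' @param n_perm Number of permutation replicates (default 100).
#' @param seed Integer seed.
#' @return List `importance` (NA when DE_full <= 0), `p`, `de_full`,
#'   `de_perm` (vector).
#' @export
permutation_importance <- function(pairs, model, variable, n_perm = 100,
                                   seed = 1) {
  stopifnot(inherits(model, "gdm_model"))
  vars <- setdiff(model$predictors, "geo")
  if (!variable %in% vars) stop("'", variable, "' is not in the model")
  de_full <- deviance_explained(model)
  emat <- .pair_env_matrix(pairs, vars)
  locs <- rownames(emat)
  set.seed(seed)
  de_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- emat
    pm[, variable] <- emat[sample(locs), variable]
    pp <- .permute_env_var(pairs, variable, pm)
    de_perm[b] <- deviance_explained(fit_gdm(pp, vars))
  }
  list(importance = if (de_full > 0)
         100 * (de_full - mean(de_perm)) / de_full else NA_real_,
       p = (1 + sum(de_perm >= de_full)) / (n_perm + 1),
       de_full = de_full, de_perm = de_perm)
}

#' Backward elimination over a candidate GDM
#'
#' Iteratively removes the variable whose removal decreases deviance
#' explained the least (ties broken by lower permutation importance, then
#' lexicographically), recording the full trajectory down to the
#' geography-only model (or stopping at `target_size`). The "inflection"
#' size -- the model size with the largest second difference in the
#' deviance-explained trajectory -- is reported as a suggestion, not
#' applied silently.
#'
#' @param pairs Site-pair table.
#' @param variables Candidate variable set (e.g. from [forward_select()]).
#' @param target_size Optional number of variables to stop at.
#' @param n_perm Permutation replicates used only for tie-breaking
#'   (default 20).
#' @param seed Integer seed.
#' @return List of class `selection_trace`: `trace` (data.frame `size`,
#'   `dropped`, `deviance_explained`), `suggested_size`, `final` (variables
#'   at `target_size` if given, else at `suggested_size`).
#' @export
backward_select <- function(pairs, variables, target_size = NULL,
                            n_perm = 20, seed = 1) {
  current <- variables
  de_cur <- deviance_explained(fit_gdm(pairs, current))
  trace <- data.frame(size = length(current), dropped = NA_character_,
                      deviance_explained = de_cur,
                      stringsAsFactors = FALSE)
  model_at_size <- list()
  model_at_size[[as.character(length(current))]] <- current
  stop_size <- if (is.null(target_size)) 0L else target_size
  while (length(current) > stop_size) {
    des <- vapply(current, function(v) {
      rest <- setdiff(current, v)
      deviance_explained(fit_gdm(pairs, rest))
    }, numeric(1))
    best_de <- max(des)
    tied <- names(des)[des > best_de - 1e-9]
    drop_var <- if (length(tied) == 1) tied else {
      model <- fit_gdm(pairs, current)
      imp <- vapply(sort(tied), function(v) {
        permutation_importance(pairs, model, v, n_perm = n_perm,
                               seed = seed)$importance
      }, numeric(1))
      imp[is.na(imp)] <- -Inf
      names(imp)[which.min(imp)]
    }
    current <- setdiff(current, drop_var)
    de_cur <- des[[drop_var]]
    trace <- rbind(trace, data.frame(size = length(current),
                                     dropped = drop_var,
                                     deviance_explained = de_cur,
                                     stringsAsFactors = FALSE))
    model_at_size[[as.character(length(current))]] <- current
  }
  de <- trace$deviance_explained
  suggested <- if (nrow(trace) >= 3) {
    # second difference over the size trajectory (sizes descend by 1)
    d2 <- de[1:(nrow(trace) - 2)] - 2 * de[2:(nrow(trace) - 1)] +
      de[3:nrow(trace)]
    trace$size[which.min(d2) + 1]
  } else trace$size[nrow(trace)]
  final_size <- if (is.null(target_size)) suggested else target_size
  structure(list(trace = trace, suggested_size = suggested,
                 final = model_at_size[[as.character(final_size)]]),
            class = "selection_trace")
}

#' Locality jackknife envelopes of GDM splines
#'
#' Each replicate removes all samples from a random `drop_fraction` of
#' localities (ceiling), rebuilds the pair table by subsetting, refits the
#' model and evaluates every predictor's spline on the full-data grid.
#'
#' @param pairs Full site-pair table.
#' @param predictors Environmental predictors of the model spec.
#' @param drop_fraction Fraction of localities removed per replicate
#'   (default 0.1).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed.
#' @param grid_n Grid resolution per predictor (default 200).
#' @return List of class `spline_envelope`: per predictor a list with `x`,
#'   `full` (full-data curve) and `reps` (replicate-by-grid matrix, NA rows
#'   for skipped replicates); plus `n_skipped`.
#' @export
jackknife_splines <- function(pairs, predictors = character(0),
                              drop_fraction = 0.1, n_reps = 100, seed = 1,
                              grid_n = 200) {
  locs <- unique(c(pairs$loc1, pairs$loc2))
  n_drop <- ceiling(drop_fraction * length(locs))
  if (length(locs) < ceiling(1 / drop_fraction)) {
    stop("need >= ", ceiling(1 / drop_fraction), " localities")
  }
  full <- fit_gdm(pairs, predictors)
  grids <- lapply(full$bases, function(b) {
    seq(b$knots[1], b$knots[3], length.out = grid_n)
  })
  out <- lapply(names(full$bases), function(p) {
    list(x = grids[[p]],
         full = gdm_spline_curve(full, p, grids[[p]])$f,
         reps = matrix(NA_real_, n_reps, grid_n))
  })
  names(out) <- names(full$bases)
  set.seed(seed)
  n_skipped <- 0L
  kept <- integer(n_reps)
  for (b in seq_len(n_reps)) {
    dropped <- sample(locs, n_drop)
    kept[b] <- length(locs) - n_drop
    sub <- pairs[!(pairs$loc1 %in% dropped | pairs$loc2 %in% dropped), ,
                 drop = FALSE]
    attr(sub, "gd_scale") <- attr(pairs, "gd_scale")
    attr(sub, "env_meta") <- attr(pairs, "env_meta")
    if (nrow(sub) < 10) {
      n_skipped <- n_skipped + 1L
      next
    }
    m <- tryCatch(fit_gdm(sub, predictors), error = function(e) NULL)
    if (is.null(m)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (p in names(full$bases)) {
      if (!is.null(m$bases[[p]])) {
        out[[p]]$reps[b, ] <- gdm_spline_curve(m, p, grids[[p]])$f
      }
    }
  }
  structure(c(out, list(n_skipped = n_skipped,
                        n_localities_kept = kept)),
            class = "spline_envelope")
}

#' Expected share of training pairs under a locality-based split
#'
#' When localities are split into training and test sets, training pairs
#' have both endpoints in training localities and test pairs at least one
#' endpoint in a test locality, so with t of L localities in training the
#' training share of pairs is C(t, 2) / C(L, 2) -- approaching
#' (1 - test_fraction)^2 (e.g. 81% for a 90/10 split) as L grows.
#'
#' @param n_localities Number of localities L.
#' @param test_fraction Fraction of localities held out; the count is
#'   `ceiling(test_fraction * L)`.
#' @return Training-pair share in (0, 1).
#' @export
train_pair_share <- function(n_localities, test_fraction = 0.1) {
  t <- n_localities - ceiling(test_fraction * n_localities)
  choose(t, 2) / choose(n_localities, 2)
}

#' Locality cross-validation of a GDM
#'
#' Localities are randomly split (1 - test_fraction) : test_fraction.
#' Training pairs have both endpoints in training localities; test pairs
#' have at least one endpoint in a test locality. The model is fitted on
#' training pairs and accuracy is the squared Pearson correlation between
#' predicted and observed test dissimilarities.
#'
#' @param pairs Site-pair table.
#' @param predictors Environmental predictors of the model spec.
#' @param test_fraction Fraction of localities held out (default 0.1).
#' @param n_reps Number of replicates (default 20).
#' @param seed Integer seed.
#' @return List `r2` (per replicate, NA when skipped), `mean_r2`,
#'   `train_share` (mean observed share of training pairs).
#' @export
cross_validate <- function(pairs, predictors = character(0),
                           test_fraction = 0.1, n_reps = 20, seed = 1) {
  locs <- unique(c(pairs$loc1, pairs$loc2))
  if (length(locs) < 10) stop("need >= 10 localities")
  n_test <- ceiling(test_fraction * length(locs))
  set.seed(seed)
  r2 <- rep(NA_real_, n_reps)
  shares <- rep(NA_real_, n_reps)
  for (b in seq_len(n_reps)) {
    test_locs <- sample(locs, n_test)
    is_test <- pairs$loc1 %in% test_locs | pairs$loc2 %in% test_locs
    train <- pairs[!is_test, , drop = FALSE]
    test <- pairs[is_test, , drop = FALSE]
    attr(train, "gd_scale") <- attr(pairs, "gd_scale")
    attr(train, "env_meta") <- attr(pairs, "env_meta")
    if (nrow(test) == 0 || nrow(train) < 10) next
    m <- tryCatch(fit_gdm(train, predictors), error = function(e) NULL)
    if (is.null(m)) next
    pred <- predict_gdm(m, test)
    if (sd(pred) == 0 || sd(test$observed) == 0) next
    r2[b] <- cor(pred, test$observed)^2
    shares[b] <- nrow(train) / nrow(pairs)
  }
  list(r2 = r2, mean_r2 = mean(r2, na.rm = TRUE),
       train_share = mean(shares, na.rm = TRUE))
}

#' Locality-permutation significance test of an environmental GDM
#'
#' Permutes the locality assignment of all environmental variables jointly
#' (geography intact), refits, and reports
#' p = (1 + #\{DE_perm >= DE_full\}) / (n_perm + 1).
#'
#' @param pairs Site-pair table.
#' @param predictors Environmental predictors (>= 1).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return List `p`, `de_full`, `de_perm`.
#' @export
model_significance <- function(pairs, predictors, n_perm = 100, seed = 1) {
  if (!length(predictors)) stop("need >= 1 environmental predictor")
  de_full <- deviance_explained(fit_gdm(pairs, predictors))
  emat <- .pair_env_matrix(pairs, predictors)
  locs <- rownames(emat)
  set.seed(seed)
  de_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- emat[sample(locs), , drop = FALSE]
    rownames(pm) <- locs
    pp <- pairs
    for (v in predictors) pp <- .permute_env_var(pp, v, pm)
    de_perm[b] <- deviance_explained(fit_gdm(pp, predictors))
  }
  list(p = (1 + sum(de_perm >= de_full)) / (n_perm + 1),
       de_full = de_full, de_perm = de_perm)
}
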