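#' Orthogonal genetic-effect scales for one biallelic locus
#'
#' Computes the intercept, additive and dominance scale vectors of the
#' NOIA (Natural and Orthogonal InterActions) parameterization for a single
#' biallelic locus. In the statistical formulation the scales are built from
#' the observed genotype frequencies \eqn{(p_{11}, p_{12}, p_{22})} of the
#' homozygous-major, heterozygous and homozygous-minor classes, which makes
#' the three design columns mutually orthogonal under those frequencies
#' regardless of Hardy-Weinberg equilibrium:
#' \deqn{x_a(g) = d(g) - (p_{12} + 2 p_{22}),}
#' where \eqn{d(g) \in \{0,1,2\}} is minor-allele dosage, and
#' \deqn{x_d = \left(\frac{-2 p_{12} p_{22}}{D},
#'                   \frac{4 p_{11} p_{22}}{D},
#'                   \frac{-2 p_{11} p_{12}}{D}\right),
#'       \quad D = p_{11} + p_{22} - (p_{11} - p_{22})^2.}
#' The functional formulation ignores the frequencies and uses the classical
#' additive-dominance scales \eqn{x_a = (-1, 0, 1)}, \eqn{x_d = (-1/2, 1/2, -1/2)}.
#'
#' @param genotypes integer vector of genotype codes (1, 2, 3; NA allowed),
#'   coded 1 = homozygous major, 2 = heterozygous, 3 = homozygous minor
#' @param formulation `"statistical"` (frequency-weighted, the default) or
#'   `"functional"`
#' @return an object of class `locus_scales`: a list with elements
#'   `freqs` (observed genotype frequencies over codes 1..3),
#'   `x_a`, `x_d` (3-vectors over genotype codes), `dominance_ok` (logical;
#'   `FALSE` when fewer than three genotype classes are observed so the
#'   dominance scale is undefined and disabled), and `status`
#'   (`"ok"`, `"two_class"` or `"monomorphic"`).
#' @examples
#' g <- c(rep(1L, 25), rep(2L, 50), rep(3L, 25))
#' s <- locus_scales(g)
#' s$x_a  # (-1, 0, 1)
#' s$x_d  # (-0.5, 0.5, -0.5)
#' @export
locus_scales <- function(genotypes, formulation = c("statistical", "functional")) {
  formulation <- match.arg(formulation)
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L) stop_invalid("no non-missing genotypes at locus")
  if (!all(g %in% GENO_CODES)) stop_invalid("genotype codes must be in {1, 2, 3}")
  counts <- tabulate(g, nbins = 3L)
  p <- counts / sum(counts)
  n_classes <- sum(counts > 0L)
  status <- if (n_classes == 3L) "ok" else if (n_classes == 2L) "two_class" else "monomorphic"

  if (formulation == "functional") {
    x_a <- c(-1, 0, 1)
    x_d <- c(-0.5, 0.5, -0.5)
  } else {
    sc <- scales_from_freqs(p)
    x_a <- sc$x_a
    x_d <- if (n_classes == 3L && all(is.finite(sc$x_d))) sc$x_d else c(0, 0, 0)
  }
  dominance_ok <- n_classes == 3L
  if (!dominance_ok) x_d <- c(0, 0, 0)
  structure(
    list(freqs = p, x_a = x_a, x_d = x_d,
         dominance_ok = dominance_ok, status = status,
         formulation = formulation),
    class = "locus_scales"
  )
}

#' @export
print.locus_scales <- function(x, ...) {
  cat("locus_scales (", x$formulation, " formulation, status: ", x$status, ")\n", sep = "")
  m <- rbind(freq = x$freqs, additive = x$x_a, dominance = x$x_d)
  colnames(m) <- c("g=1", "g=2", "g=3")
  print(round(m, 6))
  invisible(x)
}

# Pure statistical-formulation scales from genotype frequencies
# p = (p11, p12, p22) over codes (1, 2, 3). The additive scale is
# minor-allele dosage centred by its frequency-weighted mean; the dominance
# scale is the unique vector orthogonal to both intercept and additive
# scales under these frequencies (up to the conventional normalisation).
scales_from_freqs <- function(p) {
  stopifnot(length(p) == 3L)
  mu <- p[2L] + 2 * p[3L]
  x_a <- c(0, 1, 2) - mu
  D <- p[1L] + p[3L] - (p[1L] - p[3L])^2
  x_d <- c(-2 * p[2L] * p[3L], 4 * p[1L] * p[3L], -2 * p[1L] * p[2L]) / D
  list(x_a = x_a, x_d = x_d)
}

#' Construct a NOIA effect model over named loci
#'
#' A model assigns each locus one of the statuses `absent`, `additive` or
#' `dominance`; active loci contribute one design column each, and
#' optionally all products of active columns (pairwise up to the full
#' interaction) when `include_interactions` is `TRUE`.
#'
#' @param status character vector (one entry per locus, named by locus)
#'   with values in `c("absent", "additive", "dominance")`; at least one
#'   locus must be active
#' @param include_interactions include products of active single-locus
#'   columns as epistatic terms
#' @return an object of class `noia_model` with a canonical `id` built from
#'   per-locus codes 0 (absent), a (additive), d (dominance)
#' @export
noia_model <- function(status, include_interactions = FALSE) {
  if (!all(status %in% c("absent", "additive", "dominance")))
    stop_invalid("locus status must be absent, additive or dominance")
  if (is.null(names(status)))
    names(status) <- paste0("locus_", seq_along(status))
  if (all(status == "absent")) stop_invalid("at least one locus must be active")
  codes <- c(absent = "0", additive = "a", dominance = "d")[status]
  structure(
    list(status = status,
         include_interactions = isTRUE(include_interactions),
         id = paste0(paste(codes, collapse = ""),
                     if (isTRUE(include_interactions)) "+i" else "")),
    class = "noia_model"
  )
}

#' @export
print.noia_model <- function(x, ...) {
  cat("noia_model", x$id, "\n")
  print(x$status)
  invisible(x)
}

#' Enumerate the candidate NOIA model space
#'
#' All combinations of per-locus status in \{absent, additive, dominance\}
#' over `loci`, excluding the all-absent model, in a deterministic canonical
#' order (the first locus varies slowest). For three loci this yields
#' \eqn{3^3 - 1 = 26} models.
#'
#' @param loci character vector of locus names (default the three loci of
#'   the study design, ordered PLA2G4A, APOB.1, APOB.2)
#' @param include_interactions propagate the interaction flag to every model
#' @return list of [noia_model()] objects
#' @export
enumerate_models <- function(loci = c("PLA2G4A", "APOB.1", "APOB.2"),
                             include_interactions = FALSE) {
  k <- length(loci)
  stopifnot(k >= 1L)
  statuses <- c("absent", "additive", "dominance")
  grid <- do.call(expand.grid,
                  c(rev(rep(list(statuses), k)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(k)), drop = FALSE]  # first locus varies slowest
  colnames(grid) <- loci
  keep <- rowSums(grid != "absent") > 0L
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    st <- unlist(grid[i, , drop = TRUE])
    names(st) <- loci
    noia_model(st, include_interactions = include_interactions)
  })
}

# Internal: term layout of a model. Returns a list of terms, each
# list(name, loci, types) where loci indexes into the model's locus names.
model_terms <- function(model) {
  loci <- names(model$status)
  active <- which(model$status != "absent")
  main <- lapply(active, function(j) {
    type <- model$status[[j]]
    list(name = paste0(loci[j], "_", substr(type, 1, 1)),
         loci = loci[j], types = type)
  })
  terms <- main
  if (model$include_interactions && length(active) >= 2L) {
    for (size in 2:length(active)) {
      combos <- utils::combn(active, size, simplify = FALSE)
      for (cb in combos) {
        terms <- c(terms, list(list(
          name = paste(paste0(loci[cb], "_", substr(model$status[cb], 1, 1)),
                       collapse = ":"),
          loci = loci[cb], types = model$status[cb]
        )))
      }
    }
  }
  terms
}

# Internal: scale value lookup for one locus/type at genotype codes g.
scale_values <- function(scales, type, g) {
  v <- if (type == "additive") scales$x_a else scales$x_d
  v[g]
}

#' Build the NOIA design matrix for a model
#'
#' Rows are animals with complete genotypes at every active locus; columns
#' are the intercept, each active locus's additive or dominance scale
#' evaluated at that animal's genotype, and (when the model includes
#' interactions) element-wise products of the active single-locus columns.
#' Scales are computed from the genotype frequencies of the animals that
#' actually enter the design, which keeps the columns orthogonal under
#' those frequencies.
#'
#' @param genotypes integer matrix (animals x loci, codes 1/2/3/NA) with
#'   locus names as column names
#' @param model a [noia_model()] whose locus names appear in `genotypes`
#' @param formulation passed to [locus_scales()]
#' @return numeric design matrix with attributes `animals` (rownames used),
#'   `scales` (per-active-locus [locus_scales()]) and `terms`
#' @export
build_design <- function(genotypes, model,
                         formulation = c("statistical", "functional")) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(model, "noia_model"))
  loci <- names(model$status)
  missing_loci <- setdiff(loci, colnames(genotypes))
  if (length(missing_loci))
    stop_invalid("model loci absent from genotype matrix: ",
                 paste(missing_loci, collapse = ", "))
  active <- loci[model$status != "absent"]
  G <- genotypes[, active, drop = FALSE]
  complete <- rowSums(is.na(G)) == 0L
  G <- G[complete, , drop = FALSE]
  n <- nrow(G)

  scales <- lapply(active, function(l) locus_scales(G[, l], formulation))
  names(scales) <- active
  for (l in active) {
    type <- model$status[[l]]
    if (type == "dominance" && !scales[[l]]$dominance_ok)
      stop_invalid("model ", model$id, ": dominance scale undefined at locus ",
                   l, " (", scales[[l]]$status, ")")
    if (scales[[l]]$status == "monomorphic")
      stop_invalid("model ", model$id, ": locus ", l, " is monomorphic")
  }

  terms <- model_terms(model)
  X <- matrix(1, nrow = n, ncol = 1L + length(terms))
  colnames(X) <- c("(Intercept)", vapply(terms, `[[`, "", "name"))
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    col <- rep(1, n)
    for (j in seq_along(tm$loci)) {
      col <- col * scale_values(scales[[tm$loci[j]]], tm$types[j], G[, tm$loci[j]])
    }
    X[, i + 1L] <- col
  }
  if (n < ncol(X) + 1L)
    stop_invalid("model ", model$id, ": rank deficiency, ", n,
                 " usable animals for ", ncol(X), " design columns")
  rownames(X) <- rownames(G)
  attr(X, "animals") <- rownames(G)
  attr(X, "scales") <- scales
  attr(X, "terms") <- terms
  X
}

# Internal OLS workhorse: fits Y (matrix, columns = responses) on X by QR,
# returning per-response coefficient tables, Wald p-values, the whole-model
# F-test against the intercept-only model, and R^2. Constant responses are
# reported with zero effects, R^2 = 0 and model p = 1.
ols_fit <- function(X, Y) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop_invalid("rank-deficient design (rank ", qx$rank,
                                " < ", p, " columns)")
  coefs <- qr.coef(qx, Y)
  fitted <- qr.fitted(qx, Y)
  res <- Y - fitted
  df_res <- n - p
  rss <- colSums(res^2)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  d <- diag(xtx_inv)

  lapply(seq_len(ncol(Y)), function(j) {
    if (tss[j] <= 0) {
      est <- c(mean(Y[, j]), rep(0, p - 1L))
      names(est) <- colnames(X)
      return(list(estimate = est,
                  se = rep(NA_real_, p), t = rep(NA_real_, p),
                  term_p = rep(NA_real_, p),
                  model_p = 1, r_squared = 0, sigma2 = 0,
                  fitted = rep(est[1L], n), df_res = df_res))
    }
    sigma2 <- rss[j] / df_res
    se <- sqrt(sigma2 * d)
    tval <- coefs[, j] / se
    term_p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
    fstat <- ((tss[j] - rss[j]) / (p - 1L)) / sigma2
    model_p <- if (p == 1L) NA_real_
      else if (!is.finite(fstat)) 0
      else stats::pf(fstat, p - 1L, df_res, lower.tail = FALSE)
    list(estimate = coefs[, j], se = se, t = tval, term_p = term_p,
         model_p = model_p, r_squared = 1 - rss[j] / tss[j],
         sigma2 = sigma2, fitted = fitted[, j], df_res = df_res)
  })
}

#' Fit one NOIA model against one trait
#'
#' Ordinary least squares of the trait on the model's orthogonal design.
#' Animals missing the trait or any active genotype are dropped; genotype
#' frequencies (hence scales) are re-estimated from the animals entering
#' this fit, preserving within-fit orthogonality exactly.
#'
#' @param genotypes animals x loci genotype matrix (codes 1/2/3/NA)
#' @param trait numeric vector named by (or aligned with) the rows of
#'   `genotypes`
#' @param model a [noia_model()]
#' @param formulation passed to [locus_scales()]
#' @return an object of class `noia_fit`: estimates, standard errors,
#'   per-term Wald p-values, whole-model F-test p (`model_p`), `r_squared`,
#'   `n_used`, and `predicted_genotypic_effects` over the 27 joint genotype
#'   classes (with cohort occupancy; unoccupied classes have `n = 0`)
#' @export
fit_model <- function(genotypes, trait, model,
                      formulation = c("statistical", "functional")) {
  formulation <- match.arg(formulation)
  stopifnot(length(trait) == nrow(genotypes))
  trait <- as.numeric(trait)
  keep <- !is.na(trait)
  G <- genotypes[keep, , drop = FALSE]
  y <- trait[keep]
  X <- build_design(G, model, formulation)
  idx <- match(attr(X, "animals"), rownames(G))
  if (anyNA(idx)) idx <- which(rownames(G) %in% attr(X, "animals"))
  y <- y[idx]
  if (length(y) < ncol(X) + 2L)
    stop_invalid("model ", model$id, ": need at least ", ncol(X) + 2L,
                 " complete observations, have ", length(y))
  fit <- ols_fit(X, matrix(y, ncol = 1L))[[1L]]
  eff <- genotypic_effects(model, attr(X, "scales"), fit$estimate,
                           G[idx, , drop = FALSE])
  structure(
    list(model = model, formulation = formulation,
         estimate = fit$estimate, se = fit$se, t = fit$t,
         term_p = fit$term_p, model_p = fit$model_p,
         r_squared = fit$r_squared, n_used = length(y),
         scales = attr(X, "scales"),
         predicted_genotypic_effects = eff),
    class = "noia_fit"
  )
}

# Internal: predicted effect for every joint genotype class of the loci in
# the model's locus set (3^k rows, first locus varying slowest), plus the
# occupancy of each class among the fitted animals.
genotypic_effects <- function(model, scales, estimate, genotypes_used) {
  loci <- names(model$status)
  k <- length(loci)
  grid <- do.call(expand.grid,
                  c(rev(rep(list(1:3), k)), list(KEEP.OUT.ATTRS = FALSE)))
  grid <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
  colnames(grid) <- loci
  terms <- model_terms(model)
  pred <- rep(estimate[1L], nrow(grid))
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    col <- rep(1, nrow(grid))
    for (j in seq_along(tm$loci))
      col <- col * scale_values(scales[[tm$loci[j]]], tm$types[j], grid[, tm$loci[j]])
    pred <- pred + estimate[i + 1L] * col
  }
  occ <- integer(nrow(grid))
  Gu <- genotypes_used[, loci, drop = FALSE]
  cc <- Gu[rowSums(is.na(Gu)) == 0L, , drop = FALSE]
  if (nrow(cc)) {
    idc <- apply(cc, 1L, paste, collapse = "")
    idg <- apply(grid, 1L, paste, collapse = "")
    tab <- table(idc)
    occ <- as.integer(tab[idg])
    occ[is.na(occ)] <- 0L
  }
  data.frame(grid, predicted_effect = pred, n = occ,
             check.names = FALSE, row.names = NULL)
}

#' @export
print.noia_fit <- function(x, ...) {
  cat("noia_fit: model", x$model$id, "| n =", x$n_used,
      "| R^2 =", round(x$r_squared, 4),
      "| model p =", format.pval(x$model_p, digits = 4), "\n")
  tab <- data.frame(estimate = x$estimate, se = x$se, t = x$t, p = x$term_p)
  print(round(tab, 5))
  invisible(x)
}

#' Genotype-effect summary table for a fitted model
#'
#' Tabulates the NOIA-predicted phenotypic effect for each joint genotype
#' class (27 rows for a three-locus model, keyed by genotype codes in locus
#' order), together with how many fitted animals occupy each class —
#' the data behind genotype-vs-genotypic-effect panels.
#'
#' @param fit a `noia_fit` from [fit_model()]
#' @return data.frame with one genotype-code column per locus,
#'   `predicted_effect`, and occupancy `n`
#' @export
genotype_effect_table <- function(fit) {
  stopifnot(inherits(fit, "noia_fit"))
  fit$predicted_genotypic_effects
}

#' Screen every (model, trait) pair and report significant fits
#'
#' Fits each candidate model against each trait, returning a summary of
#' every testable pair, the subset with whole-model p below `alpha`, the
#' per-trait best model (lowest model p; ties broken by fewer terms, then
#' canonical model order), and the count of loci with at least one
#' significant term per fit (the basis of "k loci having an effect"
#' tabulations). Untestable pairs (rank deficiency, monomorphic locus,
#' too few complete cases) are skipped and logged in `skipped`.
#'
#' @param genotypes animals x loci genotype matrix
#' @param phenotypes data.frame with an `animal_id` column and numeric trait
#'   columns (see [read_phenotypes()]), or a numeric matrix with rownames
#' @param models list of [noia_model()]; default [enumerate_models()] over
#'   the genotype matrix's loci
#' @param alpha whole-model significance level (default 0.05)
#' @param formulation passed to [locus_scales()]
#' @return object of class `noia_screen`: list with `all`, `significant`,
#'   `best` (data.frames) and `skipped`
#' @export
screen_models <- function(genotypes, phenotypes,
                          models = enumerate_models(colnames(genotypes)),
                          alpha = 0.05,
                          formulation = c("statistical", "functional")) {
  formulation <- match.arg(formulation)
  Y <- phenotype_matrix(phenotypes)
  common <- intersect(rownames(genotypes), rownames(Y))
  if (length(common) == 0L) stop_invalid("no shared animal ids between genotypes and phenotypes")
  G <- genotypes[common, , drop = FALSE]
  Y <- Y[common, , drop = FALSE]

  rows <- list(); skipped <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    active <- names(model$status)[model$status != "absent"]
    gcomplete <- rowSums(is.na(G[, active, drop = FALSE])) == 0L
    # group traits by their missingness pattern among genotype-complete
    # animals so each pattern costs one QR decomposition
    miss <- is.na(Y[gcomplete, , drop = FALSE])
    pat <- apply(miss, 2L, function(z) paste(which(z), collapse = ","))
    for (pt in unique(pat)) {
      traits <- colnames(Y)[pat == pt]
      use <- which(gcomplete)
      if (nzchar(pt)) use <- use[-as.integer(strsplit(pt, ",")[[1L]])]
      res <- tryCatch({
        X <- build_design(G[use, , drop = FALSE], model, formulation)
        idx <- match(attr(X, "animals"), rownames(G)[use])
        Ysub <- Y[use[idx], traits, drop = FALSE]
        if (nrow(X) < ncol(X) + 2L)
          stop_invalid("too few complete observations")
        fits <- ols_fit(X, Ysub)
        list(X = X, fits = fits, traits = traits)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          model_id = model$id, traits = paste(traits, collapse = ";"),
          reason = conditionMessage(res))
        next
      }
      terms <- attr(res$X, "terms")
      term_locus <- vapply(terms, function(t)
        if (length(t$loci) == 1L) t$loci else NA_character_, "")
      for (j in seq_along(res$traits)) {
        f <- res$fits[[j]]
        sig_terms <- which(!is.na(f$term_p[-1L]) & f$term_p[-1L] < alpha)
        n_loci_eff <- length(unique(stats::na.omit(term_locus[sig_terms])))
        rows[[length(rows) + 1L]] <- data.frame(
          trait = res$traits[j], model_id = model$id, model_rank = mi,
          n_terms = ncol(res$X) - 1L,
          model_p = f$model_p, r_squared = f$r_squared,
          n_used = nrow(res$X), n_loci_with_effect = n_loci_eff,
          stringsAsFactors = FALSE)
      }
    }
  }
  all_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), model_id = character(),
               model_rank = integer(), n_terms = integer(),
               model_p = numeric(), r_squared = numeric(),
               n_used = integer(), n_loci_with_effect = integer())
  ord <- order(all_df$trait, all_df$model_p, all_df$n_terms, all_df$model_rank)
  all_df <- all_df[ord, , drop = FALSE]
  rownames(all_df) <- NULL
  best <- all_df[!duplicated(all_df$trait), , drop = FALSE]
  sig <- all_df[!is.na(all_df$model_p) & all_df$model_p < alpha, , drop = FALSE]
  structure(list(all = all_df, significant = sig, best = best,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 alpha = alpha),
            class = "noia_screen")
}

#' @export
print.noia_screen <- function(x, ...) {
  cat("noia_screen:", nrow(x$all), "fits,",
      nrow(x$significant), "significant at alpha =", x$alpha, "across",
      length(unique(x$significant$trait)), "traits\n")
  invisible(x)
}

# Internal: coerce a phenotype table (data.frame with animal_id) or a
# numeric matrix to a numeric matrix with animal-id rownames.
phenotype_matrix <- function(phenotypes) {
  if (is.matrix(phenotypes)) {
    stopifnot(!is.null(rownames(phenotypes)))
    return(phenotypes)
  }
  stopifnot(is.data.frame(phenotypes), "animal_id" %in% names(phenotypes))
  ids <- as.character(phenotypes$animal_id)
  num <- phenotypes[, setdiff(names(phenotypes), c("animal_id", "group")),
                    drop = FALSE]
  Y <- as.matrix(as.data.frame(lapply(num, as.numeric)))
  rownames(Y) <- ids
  colnames(Y) <- names(num)
  Y
}
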