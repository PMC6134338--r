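#' GSCA model specification
#'
#' Describes the structural model: one component per gene block (a weighted
#' sum of that gene's SNP dosages), one latent outcome factor (a weighted sum
#' of the phenotype measures), and one path from each gene component to the
#' factor. Significance levels for the paths are declared up front as an
#' ordered alpha sequence (sequential testing: 0.05 for the first path,
#' 0.025 for the second, by default).
#'
#' @param gene_blocks named list of SNP id vectors, one per gene component.
#' @param phenotype_block names of the measures forming the outcome factor.
#' @param alpha_sequence named numeric vector of per-path alphas, in testing
#'   order; names must match `names(gene_blocks)`.
#' @param convergence_tol stop when the criterion changes less than this.
#' @param max_iter maximum alternating-least-squares passes.
#' @return List of class `gsca_spec`.
#' @export
gsca_spec <- function(gene_blocks,
                      phenotype_block = c(
                        "nonword_repetition", "language_factor", "global_burden"
                      ),
                      alpha_sequence = c(CNTNAP2 = 0.05, NRXN1 = 0.025),
                      convergence_tol = 1e-5,
                      max_iter = 1000L) {
  stopifnot(is.list(gene_blocks), length(gene_blocks) >= 1)
  if (is.null(names(gene_blocks)) || any(names(gene_blocks) == "")) {
    stop("gene_blocks must be a named list")
  }
  all_ids <- unlist(gene_blocks)
  if (anyDuplicated(all_ids)) stop("gene blocks must be disjoint")
  structure(
    list(
      gene_blocks = gene_blocks, phenotype_block = phenotype_block,
      alpha_sequence = alpha_sequence,
      convergence_tol = convergence_tol, max_iter = as.integer(max_iter)
    ),
    class = "gsca_spec"
  )
}

#' Default GSCA specification for a SNP panel
#'
#' One gene block per gene label in the panel, in panel order.
#'
#' @param panel SNP spec table with `snp_id` and `gene` columns.
#' @param ... passed to [gsca_spec()].
#' @return A `gsca_spec`.
#' @export
gsca_spec_from_panel <- function(panel, ...) {
  blocks <- split(panel$snp_id, panel$gene)
  blocks <- blocks[unique(panel$gene)]
  gsca_spec(gene_blocks = blocks, ...)
}

#' Build standardized design matrices for a GSCA fit
#'
#' Restricts to samples with complete phenotype-block data, mean-imputes
#' missing dosages, and standardizes every column (mean 0, SD 1 with the
#' n-1 denominator). Zero-variance columns are dropped with a warning.
#'
#' @param G a [genotype_matrix()].
#' @param pheno phenotype table with a `sample_id` column.
#' @param spec a [gsca_spec()].
#' @return List of class `gsca_designs`: `Z` (named list of standardized SNP
#'   matrices per gene), `P` (standardized phenotype matrix), `sample_ids`,
#'   `n`, `dropped` and a `log` of processing notes.
#' @export
standardize_blocks <- function(G, pheno, spec) {
  stopifnot(inherits(spec, "gsca_spec"))
  ids <- intersect(rownames(G$dosage), pheno$sample_id)
  if (!length(ids)) stop("no overlapping samples between genotypes and phenotypes")
  ph <- pheno[match(ids, pheno$sample_id), spec$phenotype_block, drop = FALSE]
  complete <- stats::complete.cases(ph)
  ids <- ids[complete]
  if (!length(ids)) stop("no complete-case samples for the phenotype block")
  ph <- ph[complete, , drop = FALSE]
  log <- sprintf(
    "%d samples analysed (complete cases on %s); missing dosages mean-imputed",
    length(ids), paste(spec$phenotype_block, collapse = ", ")
  )

  std <- function(M, label) {
    M <- as.matrix(M)
    for (j in seq_len(ncol(M))) {
      mj <- M[, j]
      if (anyNA(mj)) M[is.na(mj), j] <- mean(mj, na.rm = TRUE)
    }
    sds <- apply(M, 2, stats::sd)
    keep <- which(is.finite(sds) & sds > 0)
    if (length(keep) < ncol(M)) {
      warning(sprintf(
        "dropped %d zero-variance column(s) from %s",
        ncol(M) - length(keep), label
      ))
    }
    scale(M[, keep, drop = FALSE])
  }
  Z <- lapply(names(spec$gene_blocks), function(g) {
    want <- spec$gene_blocks[[g]]
    have <- intersect(want, G$snps$snp_id)
    if (!length(have)) stop("no SNPs available for gene block ", g)
    sub <- G$dosage[ids, match(have, G$snps$snp_id), drop = FALSE]
    colnames(sub) <- have
    std(sub, g)
  })
  names(Z) <- names(spec$gene_blocks)
  P <- std(ph, "phenotype block")
  if (ncol(P) == 0) stop("phenotype block has no usable columns")
  structure(
    list(
      Z = Z, P = P, sample_ids = ids, n = length(ids),
      dropped = NULL, log = log
    ),
    class = "gsca_designs"
  )
}

# --- ALS core on crossproducts -------------------------------------------
# Blocks: gene components g_k = Z_k w_k, outcome factor f = P v, all with
# unit variance (n-1 denominator). Criterion: ||f - sum_k a_k g_k||^2 / (n-1).
# Each substep solves its subproblem exactly, so the criterion is monotone
# non-increasing across passes:
#   a  : OLS given components;
#   w_k: joint (a_k, w_k) via unconstrained OLS of the partial residual on
#        Z_k, then split into a normalized weight and a scalar path;
#   v  : norm-constrained projection (scaled projection onto colspace(P)).
.gsca_core <- function(pre, SZP, tol, max_iter) {
  K <- length(pre$blocks)
  s <- pre$s
  w <- pre$w_init
  # normalized v init
  v <- pre$v_init
  a <- rep(0, K)
  crit <- Inf
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE

  Skp <- lapply(pre$blocks, function(idx) SZP[idx, , drop = FALSE])

  comp_cov <- function(w) {
    C <- matrix(0, K, K)
    for (j in seq_len(K)) {
      for (k in j:K) {
        C[j, k] <- C[k, j] <-
          crossprod(w[[j]], pre$Szz[[j]][[k]] %*% w[[k]])[1] / s
      }
    }
    C
  }

  repeat {
    iter <- iter + 1L
    # (1) path coefficients by least squares
    Cgg <- comp_cov(w)
    Cgf <- vapply(seq_len(K), function(k) {
      crossprod(w[[k]], Skp[[k]] %*% v)[1] / s
    }, numeric(1))
    a <- tryCatch(
      solve(Cgg, Cgf),
      error = function(e) as.numeric(MASS::ginv(Cgg) %*% Cgf)
    )

    # (2) weights per gene block, jointly with the block's path
    for (k in seq_len(K)) {
      t_k <- Skp[[k]] %*% v
      for (j in seq_len(K)) {
        if (j != k) t_k <- t_k - a[j] * (pre$Szz[[k]][[j]] %*% w[[j]])
      }
      u <- pre$solve_block[[k]](t_k)
      nrm <- sqrt(max(crossprod(u, pre$Szz[[k]][[k]] %*% u)[1], 0) / s)
      if (nrm < 1e-12) next # degenerate residual: keep previous weights
      wk <- as.numeric(u) / nrm
      sgn <- sign((pre$Szz[[k]][[k]] %*% wk)[1])
      if (sgn == 0) sgn <- 1
      w[[k]] <- wk * sgn
      a[k] <- nrm * sgn
    }

    # (3) phenotype weights: scaled projection of the structural prediction
    tp <- numeric(ncol(SZP))
    for (k in seq_len(K)) tp <- tp + a[k] * as.numeric(crossprod(Skp[[k]], w[[k]]))
    vstar <- pre$solve_pp(tp)
    nrmv <- sqrt(max(crossprod(vstar, pre$Spp %*% vstar)[1], 0) / s)
    if (nrmv >= 1e-12) {
      v <- as.numeric(vstar) / nrmv
      sgnf <- sign((pre$Spp %*% v)[1])
      if (sgnf == 0) sgnf <- 1
      v <- v * sgnf
      a <- a * sgnf
    }

    # criterion with a refreshed to the exact OLS solution
    Cgg <- comp_cov(w)
    Cgf <- vapply(seq_len(K), function(k) {
      crossprod(w[[k]], Skp[[k]] %*% v)[1] / s
    }, numeric(1))
    a <- tryCatch(
      solve(Cgg, Cgf),
      error = function(e) as.numeric(MASS::ginv(Cgg) %*% Cgf)
    )
    crit_new <- 1 - 2 * sum(a * Cgf) + as.numeric(crossprod(a, Cgg %*% a))
    trace <- c(trace, crit_new)
    if (is.finite(crit) && abs(crit - crit_new) < tol) {
      crit <- crit_new
      converged <- TRUE
      break
    }
    crit <- crit_new
    if (iter >= max_iter) break
  }
  list(
    w = w, v = v, a = a, criterion = crit, trace = trace,
    iterations = iter, converged = converged
  )
}

# precompute permutation-invariant crossproducts and solvers
.gsca_precompute <- function(designs, spec) {
  Zall <- do.call(cbind, designs$Z)
  sizes <- vapply(designs$Z, ncol, integer(1))
  blocks <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  SZZ <- crossprod(Zall)
  Spp <- crossprod(designs$P)
  s <- designs$n - 1
  solver <- function(S) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) {
      function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
    } else {
      Gi <- MASS::ginv(S)
      function(b) Gi %*% b
    }
  }
  Szz <- lapply(blocks, function(bi) {
    lapply(blocks, function(bj) SZZ[bi, bj, drop = FALSE])
  })
  w_init <- lapply(seq_along(blocks), function(k) {
    wk <- rep(1, length(blocks[[k]]))
    nrm <- sqrt(crossprod(wk, Szz[[k]][[k]] %*% wk)[1] / s)
    wk / nrm
  })
  v0 <- rep(1, ncol(designs$P))
  v_init <- v0 / sqrt(crossprod(v0, Spp %*% v0)[1] / s)
  list(
    Zall = Zall, blocks = blocks, Szz = Szz, Spp = Spp, s = s,
    solve_block = lapply(seq_along(blocks), function(k) solver(Szz[[k]][[k]])),
    solve_pp = solver(Spp),
    w_init = w_init, v_init = v_init,
    snp_names = colnames(Zall), pheno_names = colnames(designs$P),
    gene_names = names(designs$Z)
  )
}

#' Fit the GSCA model by alternating least squares
#'
#' Estimates per-gene SNP weights, phenotype weights for the outcome factor
#' and the standardized gene-to-factor path coefficients. Components are
#' constrained to unit variance; each weight vector is sign-fixed so its
#' component correlates non-negatively with its first indicator. Fitting is
#' deterministic (equal-weight initialization, no randomness).
#'
#' @param spec a [gsca_spec()].
#' @param designs a `gsca_designs` object from [standardize_blocks()].
#' @return List of class `gsca_model`: `W_g` (named SNP weight vectors per
#'   gene), `v` (phenotype weights), `a_g` (named path coefficients),
#'   `criterion` (structural residual variance), `criterion_trace`,
#'   `iterations`, `converged`, `n`.
#' @export
fit_gsca <- function(spec, designs) {
  stopifnot(inherits(spec, "gsca_spec"), inherits(designs, "gsca_designs"))
  n_par <- sum(vapply(designs$Z, ncol, integer(1))) + ncol(designs$P) +
    length(designs$Z)
  if (designs$n <= n_par) {
    warning(sprintf(
      "sample size (%d) does not exceed the number of estimated weights (%d)",
      designs$n, n_par
    ))
  }
  pre <- .gsca_precompute(designs, spec)
  SZP <- crossprod(pre$Zall, designs$P)
  fit <- .gsca_core(pre, SZP, spec$convergence_tol, spec$max_iter)
  if (!fit$converged) {
    warning(sprintf("GSCA did not converge in %d iterations", fit$iterations))
  }
  W_g <- lapply(seq_along(fit$w), function(k) {
    stats::setNames(fit$w[[k]], pre$snp_names[pre$blocks[[k]]])
  })
  names(W_g) <- pre$gene_names
  structure(
    list(
      W_g = W_g,
      v = stats::setNames(fit$v, pre$pheno_names),
      a_g = stats::setNames(fit$a, pre$gene_names),
      criterion = fit$criterion,
      criterion_trace = fit$trace,
      iterations = fit$iterations,
      converged = fit$converged,
      n = designs$n
    ),
    class = "gsca_model"
  )
}

#' @export
print.gsca_model <- function(x, ...) {
  cat(sprintf(
    "<gsca_model> n=%d, criterion=%.4f, %d iterations%s\n",
    x$n, x$criterion, x$iterations,
    if (x$converged) "" else " (NOT converged)"
  ))
  print(round(x$a_g, 4))
  invisible(x)
}

#' Permutation test for the gene-to-factor paths
#'
#' Refits the GSCA model after permuting the phenotype block's sample rows
#' as a unit relative to the genotype blocks (preserving both the phenotype
#' intercorrelations and the genotype LD), and computes per-path permutation
#' p-values with the add-one estimator `p = (1 + b) / (B + 1)`.
#'
#' @param spec a [gsca_spec()].
#' @param designs a `gsca_designs` object.
#' @param B number of permutations (default 5000).
#' @param seed RNG seed controlling the permutation stream only (fitting is
#'   deterministic).
#' @param alternative `"two.sided"` (|a| comparison, default), `"less"` or
#'   `"greater"` for directional one-tailed tests.
#' @return List of class `gsca_permutation`: `model` (observed fit), `a_obs`,
#'   `null_draws` (B x paths matrix), `p_value`, `B`, `seed`, `alternative`.
#' @export
permutation_test <- function(spec, designs, B = 5000L, seed = 1L,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  B <- as.integer(B)
  if (B < 100L) warning("B < 100 permutations gives unstable p-values")
  model <- fit_gsca(spec, designs)
  pre <- .gsca_precompute(designs, spec)
  n <- designs$n

  set.seed(seed)
  K <- length(pre$blocks)
  null_draws <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    SZPb <- crossprod(pre$Zall, designs$P[perm, , drop = FALSE])
    fitb <- .gsca_core(pre, SZPb, spec$convergence_tol, spec$max_iter)
    null_draws[b, ] <- fitb$a
  }
  colnames(null_draws) <- pre$gene_names
  a_obs <- model$a_g
  p <- vapply(seq_len(K), function(k) {
    switch(alternative,
      two.sided = (1 + sum(abs(null_draws[, k]) >= abs(a_obs[k]))) / (B + 1),
      less = (1 + sum(null_draws[, k] <= a_obs[k])) / (B + 1),
      greater = (1 + sum(null_draws[, k] >= a_obs[k])) / (B + 1)
    )
  }, numeric(1))
  structure(
    list(
      model = model, a_obs = a_obs,
      null_draws = null_draws,
      p_value = stats::setNames(p, pre$gene_names),
      B = B, seed = seed, alternative = alternative
    ),
    class = "gsca_permutation"
  )
}

#' @export
print.gsca_permutation <- function(x, ...) {
  cat(sprintf(
    "<gsca_permutation> B=%d, seed=%d, %s\n", x$B, x$seed, x$alternative
  ))
  print(data.frame(
    path = names(x$a_obs), a = round(x$a_obs, 4), p = round(x$p_value, 4)
  ), row.names = FALSE)
  invisible(x)
}

#' Sequential-alpha significance verdicts for permutation results
#'
#' Compares each path's permutation p-value with its own pre-declared alpha,
#' in the declared order (for the default spec: CNTNAP2 at 0.05, then NRXN1
#' at 0.025).
#'
#' @param result a `gsca_permutation` object.
#' @param alpha_sequence named numeric vector of alphas in testing order.
#' @return Data frame with `path`, `p_value`, `alpha`, `significant` in the
#'   declared order.
#' @export
sequential_alpha_decision <- function(result,
                                      alpha_sequence = c(CNTNAP2 = 0.05, NRXN1 = 0.025)) {
  paths <- names(alpha_sequence)
  missing_paths <- setdiff(paths, names(result$p_value))
  if (length(missing_paths)) {
    stop("no p-value for path(s): ", paste(missing_paths, collapse = ", "))
  }
  extra <- setdiff(names(result$p_value), paths)
  if (length(extra)) {
    stop("no alpha declared for path(s): ", paste(extra, collapse = ", "))
  }
  data.frame(
    path = paths,
    p_value = as.numeric(result$p_value[paths]),
    alpha = as.numeric(alpha_sequence),
    significant = as.numeric(result$p_value[paths]) < as.numeric(alpha_sequence),
    stringsAsFactors = FALSE
  )
}

#' GSCA permutation analysis per cohort group and karyotype subgroup
#'
#' Runs the permutation test separately for each group label in the design
#' (SCT and the two twin subsamples), and optionally for the SCT karyotype
#' subgroups restricted to cases not ascertained via phenotype (the
#' prenatal/incidental route), mirroring the registered subgroup analysis.
#' Subgroups below the size floor are skipped with a warning.
#'
#' @param cohort list with `geno`, `pheno`, `design` (an `sct_cohort` works).
#' @param spec a [gsca_spec()].
#' @param B permutations per analysis.
#' @param seed base seed; each analysis gets a distinct derived seed.
#' @param groups group labels to analyse (default: all in the design).
#' @param karyotype_subgroups also analyse prenatally-identified SCT cases by
#'   karyotype.
#' @param min_n smallest subgroup analysed.
#' @param alternative passed to [permutation_test()].
#' @return Tidy data frame: `group`, `path`, `n`, `a`, `p_value`, `alpha`,
#'   `significant`.
#' @export
run_group_analyses <- function(cohort, spec, B = 5000L, seed = 1L,
                               groups = NULL, karyotype_subgroups = TRUE,
                               min_n = 20L,
                               alternative = "two.sided") {
  design <- cohort$design
  if (is.null(groups)) groups <- unique(stats::na.omit(design$group))
  tasks <- lapply(groups, function(g) {
    list(label = g, ids = design$sample_id[design$group %in% g])
  })
  if (karyotype_subgroups && any(design$group == "SCT", na.rm = TRUE)) {
    pre_sct <- design[
      design$group %in% "SCT" & design$ascertainment %in% "prenatal", ,
      drop = FALSE
    ]
    for (k in unique(stats::na.omit(pre_sct$karyotype))) {
      tasks <- c(tasks, list(list(
        label = paste0("SCT_", k, "_prenatal"),
        ids = pre_sct$sample_id[pre_sct$karyotype %in% k]
      )))
    }
  }
  out <- list()
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    if (length(task$ids) < min_n) {
      warning(sprintf(
        "subgroup %s has n=%d < floor %d; skipped",
        task$label, length(task$ids), min_n
      ))
      next
    }
    Gg <- subset_genotypes(cohort$geno, samples = rownames(cohort$geno$dosage) %in% task$ids)
    ph <- cohort$pheno[cohort$pheno$sample_id %in% task$ids, , drop = FALSE]
    designs <- standardize_blocks(Gg, ph, spec)
    res <- permutation_test(spec, designs,
      B = B, seed = seed + i * 1000L,
      alternative = alternative
    )
    dec <- sequential_alpha_decision(res, spec$alpha_sequence)
    out[[task$label]] <- data.frame(
      group = task$label,
      path = dec$path,
      n = designs$n,
      a = as.numeric(res$a_obs[dec$path]),
      p_value = dec$p_value,
      alpha = dec$alpha,
      significant = dec$significant,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
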