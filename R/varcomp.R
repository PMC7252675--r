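#' Topologically sort a pedigree
#'
#' @param pedigree Tibble `animal`, `sire`, `dam` (`NA` or `""` or `"0"` for
#'   unknown parents).
#' @return The pedigree tibble with parents preceding offspring.
#' @export
pedigree_sort <- function(pedigree) {
  ped <- as_tibble(pedigree)
  norm <- function(v) {
    v <- as.character(v)
    v[v %in% c("", "0")] <- NA_character_
    v
  }
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  miss <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(miss) > 0) {
    ped <- dplyr::bind_rows(tibble(animal = miss, sire = NA_character_,
                                   dam = NA_character_), ped)
  }
  if (anyDuplicated(ped$animal)) abort("duplicated animal ids in pedigree")
  depth <- setNames(rep(NA_integer_, nrow(ped)), ped$animal)
  for (pass in seq_len(nrow(ped) + 1L)) {
    changed <- FALSE
    for (i in seq_len(nrow(ped))) {
      a <- ped$animal[i]
      if (!is.na(depth[[a]])) next
      s <- ped$sire[i]; d <- ped$dam[i]
      ds <- if (is.na(s)) 0L else depth[[s]]
      dd <- if (is.na(d)) 0L else depth[[d]]
      if (!is.na(ds) && !is.na(dd)) {
        depth[[a]] <- max(ds, dd) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(depth)) abort("pedigree contains a cycle or unresolvable parentage")
  ped[order(depth[ped$animal]), , drop = FALSE]
}

#' Additive (numerator) relationship matrix
#'
#' Tabular method: diagonal is 1 plus the animal's inbreeding coefficient;
#' off-diagonals are half the sum of the relationships of an animal's parents
#' with the other animal.
#'
#' @inheritParams pedigree_sort
#' @return A dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(pedigree) {
  ped <- pedigree_sort(pedigree)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0) A[s, j] else 0) + (if (d > 0) A[d, j] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) 0.5 * A[s, d] else 0)
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding accounted for (Mendelian-sampling
#' variances use parental inbreeding coefficients taken from the tabular A).
#'
#' @inheritParams pedigree_sort
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with animal ids as
#'   dimnames, equal to `solve(build_A(pedigree))`.
#' @export
build_Ainv <- function(pedigree) {
  ped <- pedigree_sort(pedigree)
  A <- build_A(ped)
  f <- diag(A) - 1
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- if (is.na(ped$sire[i])) 0L else idx[[ped$sire[i]]]
    d <- if (is.na(ped$dam[i])) 0L else idx[[ped$dam[i]]]
    mend <- 1 - (if (s > 0) 0.25 * (1 + f[s]) else 0) -
      (if (d > 0) 0.25 * (1 + f[d]) else 0)
    a <- 1 / mend
    add(i, i, a)
    for (par in c(s, d)) {
      if (par > 0) {
        add(i, par, -a / 2); add(par, i, -a / 2)
      }
    }
    if (s > 0) add(s, s, a / 4)
    if (d > 0) add(d, d, a / 4)
    if (s > 0 && d > 0) {
      add(s, d, a / 4); add(d, s, a / 4)
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(M)
}

#' Build the mixed-model design for the repeated-records animal model
#'
#' Response and incidence matrices for
#' `y = mu + age + interval + collector + season + animal + permanent
#' environment + residual`. Season is the calendar quarter of
#' `collection_date`. Rows with missing response or covariates are dropped.
#'
#' @param data Record-level tibble.
#' @param trait Name of the response column.
#' @param pedigree Pedigree tibble covering every animal in `data`.
#' @param id Name of the animal-id column.
#' @param fixed Right-hand-side formula for the fixed effects, or `NULL` for
#'   the default model above (terms absent from `data` are skipped).
#' @return A list `y`, `X`, `Zu`, `Zp`, `Ainv`, `animals` (pedigree order),
#'   `rec_animals` (animals with records).
#' @export
build_reml_design <- function(data, trait, pedigree, id = "bull_id",
                              fixed = NULL) {
  ped <- pedigree_sort(pedigree)
  dat <- as_tibble(data)
  if (!all(dat[[id]] %in% ped$animal)) {
    abort("every record must map to a pedigreed animal")
  }
  if (is.null(fixed)) {
    terms <- character(0)
    if ("age_days" %in% names(dat)) terms <- c(terms, "age_days")
    if ("interval_days" %in% names(dat)) terms <- c(terms, "interval_days")
    if ("collector_id" %in% names(dat) &&
        dplyr::n_distinct(dat$collector_id) > 1) {
      terms <- c(terms, "factor(collector_id)")
    }
    if ("collection_date" %in% names(dat)) {
      dat$season <- quarter_of(dat$collection_date)
      if (dplyr::n_distinct(dat$season) > 1) terms <- c(terms, "factor(season)")
    }
    fixed <- stats::reformulate(if (length(terms)) terms else "1")
  }
  mf_cols <- unique(c(trait, id, all.vars(fixed)))
  dat <- dat[complete.cases(dat[intersect(mf_cols, names(dat))]), , drop = FALSE]
  y <- dat[[trait]]
  X <- model.matrix(fixed, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  rec_animals <- sort(unique(dat[[id]]))
  if (max(table(dat[[id]])) < 2) {
    abort("permanent-environment variance is unidentifiable: no animal has repeated records")
  }
  n <- nrow(dat)
  Zu <- Matrix::sparseMatrix(i = seq_len(n), j = match(dat[[id]], ped$animal),
                             x = 1, dims = c(n, nrow(ped)))
  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = match(dat[[id]], rec_animals),
                             x = 1, dims = c(n, length(rec_animals)))
  list(y = y, X = X, Zu = Zu, Zp = Zp, Ainv = build_Ainv(ped),
       animals = ped$animal, rec_animals = rec_animals)
}

#' REML variance components for the repeated-records animal model
#'
#' Maximizes the restricted likelihood over the additive-genetic,
#' permanent-environment and residual variances on Henderson's mixed-model
#' equations with the sparse pedigree inverse. The workhorse is EM-REML
#' (monotone in the restricted likelihood); by default a few EM burn-in
#' rounds are followed by average-information (AI) updates for speed, with an
#' automatic fall-back to the EM step whenever an AI step would leave the
#' parameter space or decrease the likelihood. Convergence is declared when
#' the largest relative parameter change drops below `tol`. Components are
#' floored at `1e-12` times the phenotypic variance and reported as 0 at the
#' boundary.
#'
#' @inheritParams build_reml_design
#' @param method `"ai"` (EM burn-in + AI acceleration, default) or `"em"`
#'   (pure EM).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @param em_burnin EM iterations before the first AI step.
#' @return An object of class `reml_fit`: variance components, `h2`
#'   (additive fraction of phenotypic variance), `repeatability` (additive
#'   plus permanent-environment fraction), the `-2 log` restricted-likelihood
#'   trajectory, iteration count and convergence flag.
#' @export
reml_fit <- function(data, trait, pedigree, id = "bull_id", fixed = NULL,
                     method = c("ai", "em"), tol = 1e-8, max_iter = 200L,
                     em_burnin = 3L) {
  method <- match.arg(method)
  des <- build_reml_design(data, trait, pedigree, id = id, fixed = fixed)
  fit <- reml_engine(des$y, des$X, des$Zu, des$Zp, des$Ainv,
                     method = method, tol = tol, max_iter = max_iter,
                     em_burnin = em_burnin)
  fit$trait <- trait
  fit$n_records <- length(des$y)
  fit$n_animals <- ncol(des$Zu)
  fit$n_with_records <- ncol(des$Zp)
  class(fit) <- "reml_fit"
  fit
}

reml_engine <- function(y, X, Zu, Zp, Ainv, method = "ai", tol = 1e-8,
                        max_iter = 200L, em_burnin = 3L) {
  n <- length(y)
  nf <- ncol(X)
  q <- ncol(Zu)
  qp <- ncol(Zp)
  Ainv_d <- as.matrix(Ainv)
  evmin <- NA_real_
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Zu, Zp)
  WtW <- as.matrix(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y^2)
  ui <- nf + seq_len(q)
  pi_ <- nf + q + seq_len(qp)
  ldet_A <- -2 * sum(log(Matrix::diag(Matrix::chol(Ainv))))

  vp <- var(y)
  theta <- c(g = 0.25 * vp, pe = 0.2 * vp, e = 0.55 * vp)
  floor_v <- 1e-12 * vp

  solve_mme <- function(theta) {
    C <- WtW
    C[ui, ui] <- C[ui, ui] + (theta["e"] / theta["g"]) * Ainv_d
    dg <- C[cbind(pi_, pi_)]
    C[cbind(pi_, pi_)] <- dg + theta["e"] / theta["pe"]
    U <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(U)) abort("mixed-model equations are not positive definite (non-PSD relationship matrix or unidentifiable model)")
    list(U = U, ldetC = 2 * sum(log(diag(U))))
  }
  mme_sol <- function(U, rhs) backsolve(U, backsolve(U, rhs, transpose = TRUE))

  neg2l <- function(theta, ldetC, ey) {
    (n - nf - q - qp) * log(theta["e"]) + ldet_A + q * log(theta["g"]) +
      qp * log(theta["pe"]) + ldetC + ey / theta["e"]
  }

  em_step <- function(theta, parts) {
    uhat <- parts$sol[ui]; phat <- parts$sol[pi_]
    uAu <- as.numeric(t(uhat) %*% Ainv_d %*% uhat)
    g_new <- (uAu + theta["e"] * parts$tr_u) / q
    pe_new <- (sum(phat^2) + theta["e"] * parts$tr_p) / qp
    e_new <- parts$ey / (n - nf)
    c(g = unname(g_new), pe = unname(pe_new), e = unname(e_new))
  }

  iterate_parts <- function(theta, need_traces = TRUE, mm = NULL) {
    if (is.null(mm)) mm <- solve_mme(theta)
    sol <- mme_sol(mm$U, Wty)
    ey <- yty - sum(sol * Wty)          # = y'e = sigma_e^2 * y'Py
    parts <- list(sol = sol, ey = ey, ldetC = mm$ldetC, U = mm$U)
    if (need_traces) {
      Cinv <- chol2inv(mm$U)
      parts$tr_u <- sum(Ainv_d * Cinv[ui, ui])
      parts$tr_p <- sum(diag(Cinv)[pi_ - 0L])
    }
    parts
  }

  ai_step <- function(theta, parts) {
    uhat <- parts$sol[ui]; phat <- parts$sol[pi_]
    e_res <- y - as.numeric(W %*% parts$sol)
    Py <- e_res / theta["e"]
    f <- list(
      g = as.numeric(Zu %*% (uhat / theta["g"])),
      pe = as.numeric(Zp %*% (phat / theta["pe"])),
      e = Py
    )
    Pf <- lapply(f, function(v) {
      rhs <- as.numeric(Matrix::crossprod(W, v))
      solv <- mme_sol(parts$U, rhs)
      (v - as.numeric(W %*% solv)) / theta["e"]
    })
    AI <- matrix(0, 3, 3, dimnames = list(names(f), names(f)))
    for (a in 1:3) for (b in a:3) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(f[[a]] * Pf[[b]])
    }
    uAu <- as.numeric(t(uhat) %*% Ainv_d %*% uhat)
    trP <- (n - nf - q - qp + (theta["e"] / theta["g"]) * parts$tr_u +
              (theta["e"] / theta["pe"]) * parts$tr_p) / theta["e"]
    score <- -0.5 * c(
      g = unname((q - (theta["e"] / theta["g"]) * parts$tr_u) / theta["g"] -
                   uAu / theta["g"]^2),
      pe = unname((qp - (theta["e"] / theta["pe"]) * parts$tr_p) / theta["pe"] -
                    sum(phat^2) / theta["pe"]^2),
      e = unname(trP - sum(e_res^2) / theta["e"]^2)
    )
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    theta + delta
  }

  traj <- list()
  parts <- iterate_parts(theta)
  l2 <- neg2l(theta, parts$ldetC, parts$ey)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step_kind <- "em"
    cand <- NULL
    mm_c <- NULL
    if (method == "ai" && iter > em_burnin) {
      cand <- ai_step(theta, parts)
      if (!is.null(cand) && all(cand > floor_v)) {
        mm_c <- solve_mme(cand)
        sol_c <- mme_sol(mm_c$U, Wty)
        ey_c <- yty - sum(sol_c * Wty)
        l2_c <- neg2l(cand, mm_c$ldetC, ey_c)
        if (is.finite(l2_c) && l2_c <= l2 + 1e-8) {
          step_kind <- "ai"
        } else {
          cand <- NULL
          mm_c <- NULL
        }
      } else {
        cand <- NULL
        mm_c <- NULL
      }
    }
    if (is.null(cand)) cand <- pmax(em_step(theta, parts), floor_v)
    rel <- max(abs(cand - theta) / pmax(theta, floor_v))
    theta <- cand
    parts <- iterate_parts(theta, mm = mm_c)
    l2 <- neg2l(theta, parts$ldetC, parts$ey)
    traj[[iter]] <- tibble(iter = iter, step = step_kind,
                           sigma_g2 = theta[["g"]], sigma_pe2 = theta[["pe"]],
                           sigma_e2 = theta[["e"]], neg2_loglik = unname(l2))
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  tot <- sum(theta)
  zero <- theta <= 2 * floor_v
  theta_rep <- ifelse(zero, 0, theta)
  list(
    sigma_g2 = unname(theta_rep["g"]), sigma_pe2 = unname(theta_rep["pe"]),
    sigma_e2 = unname(theta_rep["e"]),
    h2 = unname(theta_rep["g"] / tot),
    repeatability = unname((theta_rep["g"] + theta_rep["pe"]) / tot),
    loglik = unname(-0.5 * l2),
    trajectory = dplyr::bind_rows(traj),
    converged = converged, n_iter = iter, method = method
  )
}

#' Restricted log-likelihood by direct inversion of the phenotypic covariance
#'
#' Small-problem reference computation of the REML log-likelihood (up to the
#' usual additive constant) from `V = Zu A Zu' sg2 + Zp Zp' spe2 + I se2`.
#' Intended for grid searches and as an independent check of the
#' mixed-model-equations likelihood used by [reml_fit()].
#'
#' @param y,X,Zu,Zp Response and design matrices.
#' @param A Dense additive relationship matrix.
#' @param sigma Numeric vector `c(g, pe, e)` of variance components.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik_direct <- function(y, X, Zu, Zp, A, sigma) {
  Zu <- as.matrix(Zu); Zp <- as.matrix(Zp)
  V <- sigma[1] * Zu %*% A %*% t(Zu) + sigma[2] * Zp %*% t(Zp) +
    diag(sigma[3], length(y))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtVX, logarithm = TRUE)$modulus +
            as.numeric(t(y) %*% P %*% y))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): %d records, %d animals\n", x$method,
              x$n_records, x$n_animals))
  cat(sprintf("  sigma_g2 = %.4g  sigma_pe2 = %.4g  sigma_e2 = %.4g\n",
              x$sigma_g2, x$sigma_pe2, x$sigma_e2))
  cat(sprintf("  h2 = %.3f  repeatability = %.3f  (%d iterations%s)\n",
              x$h2, x$repeatability, x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}
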