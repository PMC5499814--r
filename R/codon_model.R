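# Branch-site codon substitution model.
#
# The substitution process is GY94-type: instantaneous rate pi_j * kappa
# for transitions, * omega for nonsynonymous changes, zero for
# multi-nucleotide changes.  The branch-site mixture ("model A") has four
# site classes: 0 (omega0 everywhere), 1 (neutral everywhere), 2a and 2b
# (omega0 resp. 1 on background branches, omega2 on the foreground
# branch).  The class proportions derive from (p0, p1) as
#   p2a = (1 - p0 - p1) p0 / (p0 + p1),  p2b = (1 - p0 - p1) p1 / (p0 + p1)
# which is the outer product of s = p0 + p1 and r = p0 / (p0 + p1) --
# the parameterization used internally.  The null model fixes omega2 = 1;
# the alternative frees it, and twice the log-likelihood difference is
# referred to a chi-square distribution with one degree of freedom.

#' Build a GY94 codon rate matrix
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Stationary codon frequencies over the 61 sense codons.
#' @param normalize If \code{TRUE} (default) the generator is scaled so the
#'   expected number of substitutions per codon per unit time is 1; a
#'   \code{scale_factor} shared across mixture classes may be supplied
#'   instead.
#' @param scale_factor Optional externally supplied scaling divisor.
#' @return 61 x 61 generator matrix with attributes \code{pi},
#'   \code{kappa}, \code{omega} and \code{scale_factor}.
#' @export
build_generator <- function(kappa, omega, pi = rep(1 / 61, 61),
                            normalize = TRUE, scale_factor = NULL) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be nonnegative and sum to 1")
  tab <- codon_tables()
  ty <- tab$type
  Q <- matrix(0, 61, 61)
  fac <- c(1, kappa, omega, kappa * omega) # syn tv, syn ts, ns tv, ns ts
  nz <- which(ty > 0)
  Q[nz] <- rep(pi, each = 61)[nz] * fac[ty[nz]]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  sf <- if (!is.null(scale_factor)) scale_factor
        else if (normalize) rate else 1
  Q <- Q / sf
  structure(Q, pi = pi, kappa = kappa, omega = omega, scale_factor = sf,
            rate = rate)
}

#' Transition probabilities under a codon generator
#'
#' Computes \eqn{P(t) = \exp(Qt)} by symmetric eigendecomposition,
#' exploiting the reversibility of the GY94 process.
#'
#' @param generator Matrix from [build_generator()].
#' @param t Branch length (>= 0), in the generator's time units.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_probs <- function(generator, t) {
  stopifnot(t >= 0)
  pi <- attr(generator, "pi")
  s <- sqrt(pi)
  B <- generator * outer(s, 1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- sweep(e$vectors, 1, s, "/") %*%
    (exp(e$values * t) * sweep(t(e$vectors), 2, s, "*"))
  P[P < 0] <- 0
  P
}

#' Empirical F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies estimated from the observed
#' (non-missing) codons of an alignment, combined multiplicatively and
#' renormalized over the 61 sense codons.
#'
#' @param states Integer matrix of codon states (1..61, NA for
#'   gap/missing), as stored in a codon alignment.
#' @return Frequency vector of length 61.
#' @export
codon_freq_f3x4 <- function(states) {
  tab <- codon_tables()
  obs <- states[!is.na(states)]
  if (!length(obs)) return(rep(1 / 61, 61))
  cod <- tab$codons[obs]
  cm <- do.call(rbind, strsplit(cod, ""))
  bases <- c("A", "C", "G", "T")
  f <- vapply(1:3, function(p) {
    tabp <- table(factor(cm[, p], levels = bases)) + 0.5
    as.numeric(tabp / sum(tabp))
  }, numeric(4))
  cm61 <- do.call(rbind, strsplit(tab$codons, ""))
  pi <- f[match(cm61[, 1], bases), 1] *
        f[match(cm61[, 2], bases), 2] *
        f[match(cm61[, 3], bases), 3]
  pi / sum(pi)
}

# ---- foreground branch and pruning program -------------------------------

# Identify the edge of an unrooted tree whose removal separates exactly the
# foreground leaf set from the rest.
foreground_edge <- function(tree, foreground) {
  fg <- sort(unique(foreground))
  miss <- setdiff(fg, tree$tip.label)
  if (length(miss))
    stop("foreground species not in tree: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  all_tips <- seq_len(ntip)
  fg_idx <- sort(match(fg, tree$tip.label))
  hit <- which(vapply(desc, function(d) {
    d <- sort(d)
    identical(d, fg_idx) || identical(sort(setdiff(all_tips, d)), fg_idx)
  }, logical(1)))
  if (!length(hit))
    stop("foreground does not identify a branch of the tree: ",
         paste(fg, collapse = ","))
  hit[1]
}

# Build the postorder pruning programs for the two subtrees flanking the
# foreground edge.  Edge lengths are stored per program together with the
# global edge index so they can be overwritten during branch-length
# estimation.
pruning_programs <- function(tree, fg_edge) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  lens <- tree$edge.length
  if (is.null(lens)) stop("tree has no branch lengths")
  nb <- rbind(cbind(edges, seq_len(nrow(edges))),
              cbind(edges[, 2:1], seq_len(nrow(edges))))
  adj <- split.data.frame(as.data.frame(nb[, 2:3]), nb[, 1])

  build_side <- function(root_node, avoid_node) {
    if (root_node <= ntip)
      return(list(n_nodes = 0L, tip = root_node,
                  edge_child_node = integer(0), edge_parent_node = integer(0),
                  edge_child_tip = integer(0), edge_len = numeric(0),
                  edge_gid = integer(0)))
    env <- new.env()
    env$cn <- integer(0); env$pn <- integer(0); env$ct <- integer(0)
    env$len <- numeric(0); env$gid <- integer(0); env$count <- 0L
    visit <- function(node, from) {
      kids <- adj[[as.character(node)]]
      kids <- kids[kids[[1]] != from, , drop = FALSE]
      my_edges <- integer(0)
      for (k in seq_len(nrow(kids))) {
        v <- kids[[1]][k]; eid <- kids[[2]][k]
        if (v <= ntip) {
          env$cn <- c(env$cn, 0L); env$ct <- c(env$ct, v)
        } else {
          lid <- visit(v, node)
          env$cn <- c(env$cn, lid); env$ct <- c(env$ct, 0L)
        }
        env$len <- c(env$len, lens[eid]); env$gid <- c(env$gid, eid)
        env$pn <- c(env$pn, NA_integer_)
        my_edges <- c(my_edges, length(env$pn))
      }
      env$count <- env$count + 1L
      my_id <- env$count
      env$pn[my_edges] <- my_id  # only this node's own edges
      my_id
    }
    visit(root_node, avoid_node)
    list(n_nodes = env$count, tip = 0L, edge_child_node = env$cn,
         edge_parent_node = env$pn, edge_child_tip = env$ct,
         edge_len = env$len, edge_gid = env$gid)
  }
  a <- edges[fg_edge, 1]; b <- edges[fg_edge, 2]
  list(A = build_side(a, b), B = build_side(b, a),
       t_fg = lens[fg_edge], fg_gid = fg_edge, ntip = ntip)
}

# overwrite program lengths from a global edge-length vector
set_program_lengths <- function(prog, edge_len) {
  prog$A$edge_len <- edge_len[prog$A$edge_gid]
  prog$B$edge_len <- edge_len[prog$B$edge_gid]
  prog$t_fg <- edge_len[prog$fg_gid]
  prog
}

# collapse alignment columns to unique site patterns
compress_patterns <- function(states) {
  m <- states
  m[is.na(m)] <- 0L
  key <- apply(m, 2, paste, collapse = ",")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  list(tips = m[, first, drop = FALSE], mult = as.numeric(table(idx)),
       pattern_of_col = idx)
}

# class-conditional site-pattern likelihoods (4 x npat)
class_site_lik <- function(prog, tips, pi, kappa, omega0, omega2, u,
                           only_m0 = FALSE) {
  tab <- codon_tables()
  cpp_class_site_lik(tab$type, pi, kappa, omega0, omega2, u, prog$t_fg,
                     prog$A, prog$B, tips, only_m0)
}

mixture_weights <- function(p0, p1) {
  s <- p0 + p1
  r <- p0 / s
  c(p0, p1, (1 - s) * r, (1 - s) * (1 - r))
}

#' Branch-site mixture log-likelihood
#'
#' Felsenstein-pruning likelihood of a masked codon alignment under the
#' 4-class branch-site model, with class-specific omegas on the foreground
#' branch.  Codons with gaps or N are treated as missing data (partial
#' likelihood one over all states).
#'
#' @param states Codon-state matrix (rows = species, columns = retained
#'   codon columns; values 1..61 or NA).
#' @param tree Unrooted \code{phylo} with branch lengths covering the
#'   alignment's species.
#' @param foreground Character vector of foreground leaf species (one
#'   species for a terminal branch, several for an internal clade).
#' @param p0,p1,omega0,omega2 Branch-site parameters; \code{omega2 = 1}
#'   gives the null model.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default F3x4 from the alignment).
#' @param scale Multiplier applied to all branch lengths.
#' @return Log-likelihood (scalar); \code{-Inf} for impossible data (for
#'   example a zero-length tree with non-identical sequences).
#' @export
branch_site_loglik <- function(states, tree, foreground, p0, p1, omega0,
                               omega2 = 1, kappa = 2,
                               pi = codon_freq_f3x4(states), scale = 1) {
  tree <- match_tree_alignment(tree, rownames(states))
  prog <- pruning_programs(tree, foreground_edge(tree, foreground))
  pat <- compress_patterns(states[tree$tip.label, , drop = FALSE])
  cl <- class_site_lik(prog, pat$tips, pi, kappa, omega0, omega2, scale)
  w <- mixture_weights(p0, p1)
  site <- as.numeric(w %*% cl)
  if (any(site <= 0)) return(-Inf)
  sum(pat$mult * log(site))
}

# prune tree to alignment species (keeping it unrooted)
match_tree_alignment <- function(tree, species) {
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop("alignment species missing from tree: ", paste(miss, collapse = ", "))
  if (length(setdiff(tree$tip.label, species))) {
    tree <- ape::keep.tip(tree, species)
    if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  }
  tree
}

# ---- maximum-likelihood fitting ------------------------------------------

# inner profile optimization over the mixture proportions (p0, p1) for a
# fixed 4 x npat class-likelihood matrix; warm-started
.fit_mixture <- function(cl, mult, start = c(0.8, 1.2)) {
  obj <- function(x) {
    s <- stats::plogis(x[1]); r <- stats::plogis(x[2])
    w <- c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
    site <- as.numeric(w %*% cl)
    if (any(site <= 0)) return(1e10)
    -sum(mult * log(site))
  }
  # the warm start is pulled off the s = p0+p1 = 1 boundary (where the
  # foreground omega has zero gradient) and an interior start is always
  # tried as well
  starts <- list(c(min(start[1], 3), start[2]), c(1.4, start[2]))
  ops <- lapply(starts, function(st)
    stats::optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 120, reltol = 1e-9)))
  op <- ops[[which.min(vapply(ops, `[[`, 0, "value"))]]
  s <- stats::plogis(op$par[1]); r <- stats::plogis(op$par[2])
  list(p0 = s * r, p1 = s * (1 - r), nll = op$value, par = op$par)
}

#' Fit the branch-site model (null, alternative or single-ratio M0)
#'
#' Maximum-likelihood fit by bounded quasi-Newton over omega0, the tree
#' scale and (alternative model) omega2, with the class proportions
#' profiled out by an inner simplex optimization, using deterministic
#' multi-starts; kappa is estimated under an M0 pre-fit and then held
#' fixed.  Relative branch lengths are taken from the supplied tree
#' and scaled by a single free factor (set
#' \code{estimate_branch_lengths = TRUE} under \code{variant = "m0"} for a
#' full per-branch fit by coordinate descent).
#'
#' @inheritParams branch_site_loglik
#' @param variant \code{"null"}, \code{"alternative"} or \code{"m0"}.
#' @param kappa Fixed kappa, or \code{NULL} to estimate it.
#' @param estimate_branch_lengths For \code{variant = "m0"}: refine every
#'   branch length individually after the global fit.
#' @param n_starts Number of deterministic starts for the alternative fit.
#' @return List with the fitted parameters, \code{lnL}, the per-pattern
#'   class likelihood matrix, pattern bookkeeping and a convergence flag.
#' @export
fit_branch_site <- function(states, tree, foreground,
                            variant = c("alternative", "null", "m0"),
                            pi = codon_freq_f3x4(states), kappa = NULL,
                            estimate_branch_lengths = FALSE, n_starts = 3) {
  variant <- match.arg(variant)
  tree <- match_tree_alignment(tree, rownames(states))
  prog <- pruning_programs(tree, foreground_edge(tree, foreground))
  pat <- compress_patterns(states[tree$tip.label, , drop = FALSE])
  fit_kappa <- is.null(kappa)
  kap0 <- if (fit_kappa) 2 else kappa

  if (variant == "m0") {
    res <- .fit_m0(prog, pat, pi, kap0, fit_kappa, tree,
                   estimate_branch_lengths)
    return(res)
  }

  mix_env <- new.env()
  mix_env$start <- c(0.8, 1.2)
  # kappa is estimated once under M0 and then held fixed in the null and
  # alternative fits (it is nearly orthogonal to the selection parameters)
  m0 <- .fit_m0(prog, pat, pi, kap0, fit_kappa, tree, FALSE)
  kap_use <- m0$kappa
  eval_outer <- function(lw0, lu, lw2) {
    cl <- class_site_lik(prog, pat$tips, pi, kap_use, exp(lw0), exp(lw2),
                         exp(lu))
    fit <- .fit_mixture(cl, pat$mult, mix_env$start)
    mix_env$start <- fit$par
    mix_env$last <- list(cl = cl, p0 = fit$p0, p1 = fit$p1)
    fit$nll
  }
  lb <- c(log(1e-4), log(1e-3))
  ub <- c(log(1), log(1e3))
  w0_start <- min(max(m0$omega, 1.5e-4), 0.99)
  base_par <- c(log(w0_start), log(m0$scale))

  multistart <- function(starts, obj, lower, upper) {
    fits <- lapply(starts, function(s)
      tryCatch(stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 6, factr = 1e10)),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    tryCatch(stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(maxit = 35, factr = 1e8)),
             error = function(e) best)
  }

  # null model: omega2 fixed at 1
  starts0 <- list(base_par,
                  c(log(0.05), base_par[2]),
                  c(log(0.5), base_par[2]))[seq_len(max(1, n_starts))]
  obj0 <- function(x) eval_outer(x[1], x[2], log(1))
  op0 <- multistart(starts0, obj0, lb, ub)
  x0 <- op0$par
  nll0 <- obj0(x0)
  last <- mix_env$last
  null_fit <- list(variant = "null", lnL = -nll0, p0 = last$p0,
                   p1 = last$p1, omega0 = exp(x0[1]), kappa = kap_use,
                   omega2 = 1, scale = exp(x0[2]), class_lik = last$cl,
                   pattern = pat, pi = pi, tree = tree,
                   converged = op0$convergence %in% c(0, 1))
  if (variant == "null") return(null_fit)

  # alternative: omega2 free in [1, 999]; the first start sits at the null
  # solution so lnL(alt) >= lnL(null) up to optimizer tolerance
  lb3 <- c(lb, log(1 + 1e-8)); ub3 <- c(ub, log(999))
  starts <- list(c(x0, log(1 + 1e-6)), c(x0, log(4.8)), c(x0, log(25)))
  starts <- starts[seq_len(max(1, min(n_starts, length(starts))))]
  obj <- function(x) eval_outer(x[1], x[2], x[3])
  polish <- multistart(starts, obj, lb3, ub3)
  conv <- !is.null(polish)
  x <- polish$par
  nll <- obj(x)
  last <- mix_env$last
  lnL <- -nll
  # guard against optimizer asymmetry: re-polish the null from the
  # alternative's (omega0, scale) basin; the LRT must only measure the
  # omega2 contrast, not a better basin found by one of the two fits
  op0b <- tryCatch(stats::optim(x[1:2], obj0, method = "L-BFGS-B",
                                lower = lb, upper = ub,
                                control = list(maxit = 30, factr = 1e8)),
                   error = function(e) NULL)
  if (!is.null(op0b) && -op0b$value > null_fit$lnL) {
    nll0b <- obj0(op0b$par)
    last0 <- mix_env$last
    null_fit$lnL <- -nll0b
    null_fit$p0 <- last0$p0; null_fit$p1 <- last0$p1
    null_fit$omega0 <- exp(op0b$par[1]); null_fit$scale <- exp(op0b$par[2])
    null_fit$class_lik <- last0$cl
    x0 <- op0b$par
  }
  if (lnL < null_fit$lnL) { # numeric safeguard: alternative nests the null
    x <- c(x0, log(1))
    nll <- obj(x)
    last <- mix_env$last
    lnL <- max(-nll, null_fit$lnL)
  }
  list(variant = "alternative", lnL = lnL, p0 = last$p0, p1 = last$p1,
       omega0 = exp(x[1]), kappa = kap_use, omega2 = exp(x[3]),
       scale = exp(x[2]), class_lik = last$cl, pattern = pat, pi = pi,
       tree = tree, null = null_fit,
       converged = conv && polish$convergence %in% c(0, 1))
}

# single-ratio M0 fit; optionally refines every branch length by Brent
# coordinate descent (used for branch-length recovery)
.fit_m0 <- function(prog, pat, pi, kap0, fit_kappa, tree,
                    estimate_branch_lengths) {
  m0_nll <- function(lw, lk, lu, pr = prog) {
    cl <- class_site_lik(pr, pat$tips, pi, exp(lk), exp(lw), 1, exp(lu),
                         only_m0 = TRUE)
    site <- cl[1, ]
    if (any(site <= 0)) return(1e10)
    -sum(pat$mult * log(site))
  }
  lb <- c(log(1e-4), log(0.2), log(1e-3))
  ub <- c(log(20), log(50), log(1e3))
  obj <- function(x) m0_nll(x[1], if (fit_kappa) x[2] else log(kap0), x[3])
  op <- stats::optim(c(log(0.2), log(kap0), log(1)), obj, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(maxit = 50, factr = 1e8))
  x <- op$par
  kappa <- if (fit_kappa) exp(x[2]) else kap0
  out <- list(variant = "m0", lnL = -op$value, omega = exp(x[1]),
              kappa = kappa, scale = exp(x[3]), tree = tree,
              converged = op$convergence == 0)
  if (estimate_branch_lengths) {
    u <- exp(x[3])
    el <- tree$edge.length * u
    pr <- set_program_lengths(prog, el)
    lw <- x[1]; lk <- log(kappa)
    for (sweep in 1:2) {
      for (e in seq_along(el)) {
        f <- function(t) {
          el2 <- el; el2[e] <- t
          m0_nll(lw, lk, log(1), set_program_lengths(prog, el2))
        }
        opt <- stats::optimize(f, c(max(1e-8, el[e] / 5), el[e] * 5 + 0.05),
                               tol = 1e-6)
        el[e] <- opt$minimum
      }
      # re-optimize omega given the new lengths
      oo <- stats::optimize(function(w)
        m0_nll(log(w), lk, log(1), set_program_lengths(prog, el)),
        c(1e-4, 5), tol = 1e-6)
      lw <- log(oo$minimum)
    }
    tr2 <- tree
    tr2$edge.length <- el
    out$tree_ml <- tr2
    out$omega <- exp(lw)
    out$lnL <- -m0_nll(lw, lk, log(1), set_program_lengths(prog, el))
    out$scale <- 1
  }
  out
}

#' Likelihood-ratio test for positive selection
#'
#' @param lnL0,lnL1 Log-likelihoods of the null and alternative branch-site
#'   fits.
#' @return List with the clamped statistic \code{2(lnL1 - lnL0)} and the
#'   p-value from a chi-square distribution with one degree of freedom.
#' @export
lrt <- function(lnL0, lnL1) {
  stopifnot(is.finite(lnL0), is.finite(lnL1))
  stat <- max(0, 2 * (lnL1 - lnL0))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Posterior probabilities of the positively selected site classes
#'
#' Naive empirical Bayes: class posteriors at the maximum-likelihood
#' parameter estimates; the reported value per alignment column is the
#' posterior mass of classes 2a and 2b.
#'
#' @param fit An \code{"alternative"} fit from [fit_branch_site()].
#' @return Numeric vector over alignment columns, in (0, 1).
#' @export
site_posteriors <- function(fit) {
  w <- mixture_weights(fit$p0, fit$p1)
  cl <- fit$class_lik
  num <- w * cl
  tot <- colSums(num)
  post <- (num[3, ] + num[4, ]) / tot
  post[fit$pattern$pattern_of_col]
}
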