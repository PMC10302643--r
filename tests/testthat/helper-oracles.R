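# Independent reference implementations used as oracles. These deliberately
# use naive double loops / exhaustive enumeration and share no code with the
# package internals they check.

# Eqs-style message passing with explicit neighbor loops
naiveMpnn <- function(graph, params) {
  E <- edgeOrder(graph)
  n <- nrow(E)
  h <- c(1, nodePresence(graph))
  s <- params@leakySlope
  lk <- function(x) ifelse(x >= 0, x, s * x)
  for (t in seq_len(params@iterations)) {
    m <- matrix(0, nrow(params@Wm), n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (E[i, j] > 0)
      m[, i] <- m[, i] + lk(params@Wm %*% c(h[i], h[j], E[i, j]))
    h2 <- numeric(n)
    for (i in seq_len(n))
      h2[i] <- if (params@updateLeaky) lk(sum(params@Wu * c(h[i], m[, i])))
               else sum(params@Wu * c(h[i], m[, i]))
    h <- h2
  }
  h[-1]
}

# scalar-by-scalar two-head readout
naiveForward <- function(gnnOut, hammett, head, T = 298.15) {
  sg <- function(x) 1 / (1 + exp(-x))
  a1 <- sum(head@wH1 * c(hammett, gnnOut))
  a2 <- sum(head@wH2 * gnnOut)
  dG_LS <- head@wFinal[["LS"]] * sg(a1)
  dG_L <- head@wFinal[["L"]] * sg(a2)
  kB <- 1.380649e-23; hP <- 6.62607015e-34; R <- 8.314462618 / 4184
  list(dG_LS = dG_LS, dG_L = dG_L, dG_total = dG_LS + dG_L,
       k_pred = kB * T / hP * exp(-(dG_LS + dG_L) / (R * T)))
}

# exhaustive active-set NNLS: tries every support, keeps the feasible fit
# with the smallest residual sum of squares
enumNnls <- function(X, y) {
  p <- ncol(X)
  best <- list(coef = numeric(p), rss = sum(y^2))
  for (sz in seq_len(p)) {
    for (S in utils::combn(p, sz, simplify = FALSE)) {
      cf <- tryCatch(qr.coef(qr(X[, S, drop = FALSE]), y),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf) || any(cf < 0)) next
      r <- y - X[, S, drop = FALSE] %*% cf
      rss <- sum(r^2)
      if (rss < best$rss - 1e-12) {
        co <- numeric(p); co[S] <- cf
        best <- list(coef = co, rss = rss)
      }
    }
  }
  best$coef
}

# small canonical fixtures shared across tests
fixtureTrees <- function() ligandFixtures()

smallTemplate <- function() {
  buildTemplate(list(buildTree(c("Et", "Me", "Me"), "EtMe2"),
                     buildTree(c("Me", "Me", "Me"), "PMe3")))
}

# tiny synthetic world used by training tests
tinyWorld <- function(nLig = 4, nSub = 5, seed = 1,
                      truth = generativeTruth(seed = seed + 2)) {
  trees <- generateLigandSet(nLig, seed = seed)
  subs <- generateSubstituentSet(nSub, seed = seed + 1)
  ds <- generateReactionDataset(trees, subs$substrates, truth)
  list(trees = trees, subs = subs, reactions = ds$reactions,
       truth = ds$truth)
}
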