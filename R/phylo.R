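#' Parse a newick tree with branch lengths
#'
#' Thin wrapper around \code{ape::read.tree} adding the checks the contrast
#' machinery relies on: every non-root edge must carry a finite, non-negative
#' branch length; leaf labels must be unique. Polytomies are permitted at
#' parse time but flagged (attribute \code{"polytomy"}), since contrasts
#' require a bifurcating tree.
#'
#' @param text newick string (used when \code{file} is NULL).
#' @param file optionally, path to a newick file.
#' @return An \code{ape} \code{phylo} object with attribute
#'   \code{"polytomy"} (logical).
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' attr(tr, "polytomy")  # FALSE
#' @export
parseNewick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) {
    if (!file.exists(file)) stop("file not found: ", file)
    tryCatch(ape::read.tree(file), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick (unbalanced parentheses or empty input)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name '",
         tree$tip.label[duplicated(tree$tip.label)][1], "'")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("missing branch lengths")
  if (any(!is.finite(tree$edge.length)))
    stop("missing or non-finite branch length on ",
         sum(!is.finite(tree$edge.length)), " edge(s)")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  attr(tree, "polytomy") <- !ape::is.binary(tree)
  tree
}

#' Replace zero-length branches
#'
#' Felsenstein contrasts divide by branch lengths, so zero-length branches
#' must be given a small positive value. The default policy replaces every
#' zero branch with half the length of the shortest non-zero branch; a fixed
#' replacement value can be supplied instead.
#'
#' @param tree a \code{phylo} object.
#' @param policy \code{"half_min_positive"} (default) or \code{"fixed"}.
#' @param value replacement length when \code{policy = "fixed"}.
#' @return The tree with all branch lengths positive. Trees without zero
#'   branches are returned unchanged.
#' @examples
#' tr <- parseNewick("((A:0,B:0.00006):0.5,C:0.5);")
#' adjustZeroBranches(tr)$edge.length  # zero branch becomes 0.00003
#' @export
adjustZeroBranches <- function(tree, policy = c("half_min_positive", "fixed"),
                               value = NULL) {
  policy <- match.arg(policy)
  zero <- tree$edge.length == 0
  if (!any(zero)) return(tree)
  if (all(zero)) stop("all branches have length zero")
  repl <- if (policy == "fixed") {
    if (is.null(value) || value <= 0) stop("fixed policy needs a positive value")
    value
  } else {
    min(tree$edge.length[!zero]) / 2
  }
  tree$edge.length[zero] <- repl
  tree
}

#' Felsenstein's phylogenetically independent contrasts
#'
#' Standardized contrasts under the Brownian-motion model, computed by the
#' classic pruning recursion. At an internal node whose two children carry
#' values x1, x2 on (possibly extended) branches v1, v2:
#' contrast = (x1 - x2)/sqrt(v1 + v2); the node is assigned the
#' precision-weighted value (x1/v1 + x2/v2)/(1/v1 + 1/v2) and its parent
#' branch is extended by v1*v2/(v1 + v2). Child order for the subtraction is
#' the order in which children appear in the newick string, so contrast
#' signs are reproducible; relabeling children flips signs but leaves every
#' downstream statistic unchanged.
#'
#' @param tree rooted, fully bifurcating \code{phylo} with strictly positive
#'   branch lengths (see \code{\link{adjustZeroBranches}}). Trees with
#'   polytomies are rejected unless \code{resolvePolytomies = TRUE}, in which
#'   case they are arbitrarily resolved into zero-length branches which are
#'   then adjusted by the half-min rule.
#' @param trait named numeric vector, species -> trait value; must cover all
#'   leaves.
#' @param name trait name stored in the result.
#' @param resolvePolytomies logical.
#' @return A \linkS4class{ContrastSet} with n_leaves - 1 contrasts, ordered
#'   by internal node number.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' contrastValues(independentContrasts(tr, c(A = 3, B = 1, C = 0)))
#' @export
independentContrasts <- function(tree, trait, name = "trait",
                                 resolvePolytomies = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.binary(tree)) {
    if (!resolvePolytomies)
      stop("tree has polytomies; resolve them or set resolvePolytomies = TRUE")
    tree <- ape::multi2di(tree)
    tree <- adjustZeroBranches(tree)
  }
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive (see adjustZeroBranches)")
  tips <- tree$tip.label
  missing <- setdiff(tips, names(trait))
  if (length(missing))
    stop("missing trait value for species: ", paste(missing, collapse = ", "))
  nTip <- length(tips)
  if (nTip < 2) stop("need at least 2 species")
  tree <- stats::reorder(tree, "cladewise")
  nNode <- tree$Nnode
  root <- nTip + 1L

  ## working arrays over node ids 1..nTip+nNode
  value <- c(as.numeric(trait[tips]), rep(NA_real_, nNode))
  edgeLen <- numeric(nTip + nNode)
  parentEdge <- match(seq_len(nTip + nNode), tree$edge[, 2])
  edgeLen[!is.na(parentEdge)] <- tree$edge.length[parentEdge[!is.na(parentEdge)]]

  ## depth of every node (cladewise order sets parents before children)
  depth <- rep(0L, nTip + nNode)
  for (e in seq_len(nrow(tree$edge)))
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1L
  internal <- seq.int(root, nTip + nNode)
  postorder <- internal[order(depth[internal], decreasing = TRUE)]

  contrasts <- numeric(0)
  nodeIds <- integer(0)
  ## deepest nodes first; children in edge-matrix (= newick) order
  for (node in postorder) {
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(ch) != 2L) stop("internal error: non-binary node ", node)
    x1 <- value[ch[1]]; x2 <- value[ch[2]]
    v1 <- edgeLen[ch[1]]; v2 <- edgeLen[ch[2]]
    contrasts <- c(contrasts, (x1 - x2) / sqrt(v1 + v2))
    nodeIds <- c(nodeIds, node)
    value[node] <- (x1 / v1 + x2 / v2) / (1 / v1 + 1 / v2)
    edgeLen[node] <- edgeLen[node] + v1 * v2 / (v1 + v2)
  }
  ord <- order(nodeIds)
  new("ContrastSet", contrasts = contrasts[ord],
      nodes = as.character(nodeIds[ord]), trait = name)
}

## extract paired contrast vectors, checking node alignment
pairedContrasts <- function(cx, cy) {
  x <- if (is(cx, "ContrastSet")) cx@contrasts else as.numeric(cx)
  y <- if (is(cy, "ContrastSet")) cy@contrasts else as.numeric(cy)
  if (is(cx, "ContrastSet") && is(cy, "ContrastSet") &&
      !identical(cx@nodes, cy@nodes))
    stop("contrast sets are indexed by different nodes")
  if (length(x) != length(y)) stop("contrast sets differ in length")
  if (length(x) < 2) stop("need at least 2 contrasts")
  list(x = x, y = y)
}

#' Through-origin correlation of two contrast sets
#'
#' R = sum(x*y) / sqrt(sum(x^2) * sum(y^2)). Because the sign of each
#' contrast is arbitrary (it depends on child order), the regression of one
#' contrast on another must pass through the origin; R is invariant to
#' flipping the sign of any (x, y) pair jointly. With \code{positivize},
#' pairs are sign-flipped so x >= 0 before any per-pair diagnostics are
#' taken; R itself is unchanged.
#'
#' @param cx,cy \linkS4class{ContrastSet}s over the same nodes (or bare
#'   numeric vectors).
#' @param positivize logical.
#' @return The through-origin correlation (numeric scalar).
#' @export
contrastCorrelation <- function(cx, cy, positivize = FALSE) {
  p <- pairedContrasts(cx, cy)
  x <- p$x; y <- p$y
  if (positivize) {
    s <- ifelse(x < 0, -1, 1)
    x <- x * s; y <- y * s
  }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0)
    stop("through-origin correlation undefined for an all-zero contrast vector")
  sum(x * y) / sqrt(sx * sy)
}

## t-distribution p for a through-origin correlation of n contrasts
## (df = n - 1: no intercept is estimated)
contrastCorrelationP <- function(R, n, sides = "two") {
  df <- n - 1
  t <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  switch(sides,
         two = 2 * pt(-abs(t), df),
         greater = pt(t, df, lower.tail = FALSE),
         less = pt(t, df))
}

#' Randomization test for the contrast correlation
#'
#' Shuffles the association between the two contrast vectors: one vector is
#' permuted uniformly \code{nPerm} times with a seeded generator and the
#' through-origin correlation recomputed each time. The exceedance count k
#' is the number of permuted correlations at least as extreme as the
#' observed one, one-sided in the direction of the observed R (R_rand >= R
#' when R >= 0, R_rand <= R otherwise). Treating the observed data as one
#' additional randomization, p = (k + 1)/(N + 1).
#'
#' An alternative null that flips contrast signs at random instead of
#' permuting is available (\code{nullModel = "signflip"}) but permutation is
#' the default.
#'
#' @inheritParams contrastCorrelation
#' @param nPerm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param nullModel \code{"permute"} or \code{"signflip"}.
#' @return A \linkS4class{RandomizationResult}.
#' @export
randomizationPvalue <- function(cx, cy, nPerm = 9999, seed = 1L,
                                nullModel = c("permute", "signflip")) {
  nullModel <- match.arg(nullModel)
  p <- pairedContrasts(cx, cy)
  x <- p$x; y <- p$y
  robs <- contrastCorrelation(x, y)
  sx <- sqrt(sum(x^2))
  set.seed(as.integer(seed))
  rrand <- vapply(seq_len(nPerm), function(i) {
    yp <- if (nullModel == "permute") sample(y)
          else y * sample(c(-1, 1), length(y), replace = TRUE)
    sum(x * yp) / (sx * sqrt(sum(yp^2)))
  }, numeric(1))
  k <- if (robs >= 0) sum(rrand >= robs) else sum(rrand <= robs)
  RandomizationResult(robs, nPerm, k, seed = as.integer(seed))
}

#' Naive and phylogenetically corrected per-amino-acid temperature profile
#'
#' For each of the 20 amino acids, correlates its proteome-wide fraction
#' with species temperature twice: naively (ordinary Pearson correlation
#' across species, p from the t distribution) and with the comparative
#' method (through-origin correlation of independent contrasts, p from the
#' t distribution with n_contrasts - 1 degrees of freedom, or from the
#' permutation null on request). Closely related species share both
#' composition and habitat by descent, so the two columns can disagree
#' sharply — which is the point of the comparison.
#'
#' @param proteomes named list (species -> \code{AAStringSet} or character
#'   vector of proteins).
#' @param traits data.frame with columns species, temperature (see
#'   \code{\link{readTraitTable}}), or a named numeric vector.
#' @param tree optional rooted bifurcating \code{phylo}; when NULL the
#'   comparative columns are NA.
#' @param randomizationP use the permutation null for the comparative p.
#' @param nPerm,seed randomization parameters.
#' @return data.frame: aminoAcid, R, p, RComp, pComp.
#' @export
perAaTemperatureProfile <- function(proteomes, traits, tree = NULL,
                                    randomizationP = FALSE, nPerm = 9999,
                                    seed = 1L) {
  temp <- traitVector(traits)
  spp <- names(proteomes)
  if (is.null(spp)) stop("proteomes must be a named list")
  missing <- setdiff(spp, names(temp))
  if (length(missing))
    stop("species without temperature: ", paste(missing, collapse = ", "))
  if (length(spp) < 3) stop("need at least 3 species")
  temp <- temp[spp]

  freqMat <- vapply(proteomes, function(p) {
    f <- proteomeFrequencies(p)
    as.numeric(f)
  }, numeric(length(AA20)))
  rownames(freqMat) <- AA20

  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, spp)
    lacking <- setdiff(spp, tree$tip.label)
    if (length(extra) || length(lacking))
      stop("tree/species mismatch; only in tree: [",
           paste(extra, collapse = ", "), "]; only in panel: [",
           paste(lacking, collapse = ", "), "]")
    ct <- independentContrasts(tree, temp, name = "temperature")
  }

  out <- data.frame(aminoAcid = AA20, R = NA_real_, p = NA_real_,
                    RComp = NA_real_, pComp = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(AA20)) {
    f <- freqMat[i, spp]
    if (sd(f) > 0) {
      ct0 <- cor.test(f, temp, method = "pearson")
      out$R[i] <- unname(ct0$estimate)
      out$p[i] <- ct0$p.value
    }
    if (!is.null(tree) && sd(f) > 0) {
      cf <- independentContrasts(tree, setNames(f, spp), name = AA20[i])
      R <- contrastCorrelation(cf, ct)
      out$RComp[i] <- R
      out$pComp[i] <- if (randomizationP) {
        pValue(randomizationPvalue(cf, ct, nPerm = nPerm, seed = seed))
      } else {
        contrastCorrelationP(R, length(cf@contrasts))
      }
    }
  }
  out
}

## accept a trait table data.frame or a named numeric vector
traitVector <- function(traits, column = "temperature") {
  if (is.data.frame(traits)) {
    setNames(traits[[column]], traits$species)
  } else if (is.numeric(traits) && !is.null(names(traits))) {
    traits
  } else {
    stop("traits must be a trait table or a named numeric vector")
  }
}
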