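#' @include AllClasses.R constructors.R
NULL

.dagParents <- function(dag) {
  # adjacency lists keyed by term
  p <- split(dag@edges[, "parent"], factor(dag@edges[, "child"], levels = dag@terms))
  lapply(p, unique)
}

.dagChildren <- function(dag) {
  c_ <- split(dag@edges[, "child"], factor(dag@edges[, "parent"], levels = dag@terms))
  lapply(c_, unique)
}

#' Ancestor closure of a disease term
#'
#' Returns the term together with every ancestor reachable along
#' child -> parent edges (the node set of the term's own sub-DAG).
#'
#' @param dag a [DiseaseDAG-class].
#' @param term a term identifier in `dag`.
#' @return character vector of term identifiers (unordered set).
#' @export
ancestorSet <- function(dag, term) {
  if (!term %in% dag@terms)
    stop("unknown term: ", term)
  parents <- .dagParents(dag)
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# contributions of every member of T(root) to root, as a named vector:
# 1 for root itself, else delta * max over the node's children inside T(root).
.contributions <- function(dag, root, cfg) {
  Tset <- ancestorSet(dag, root)
  children <- .dagChildren(dag)
  memo <- new.env(parent = emptyenv())
  assign(root, 1, envir = memo)
  rec <- function(node) {
    if (exists(node, envir = memo, inherits = FALSE))
      return(get(node, envir = memo, inherits = FALSE))
    kids <- intersect(children[[node]], Tset)
    # every non-root member of T(root) has at least one child in T(root)
    v <- cfg@delta * max(vapply(kids, rec, numeric(1)))
    assign(node, v, envir = memo)
    v
  }
  vapply(Tset, rec, numeric(1))
}

#' Semantic contribution of an ancestor to a disease term
#'
#' The decaying contribution D1 of `node` to `root`: 1 when
#' `node == root`, otherwise `delta` times the maximum contribution over
#' `node`'s children that lie in the ancestor closure of `root`.
#'
#' @param dag a [DiseaseDAG-class].
#' @param root the disease term whose sub-DAG is considered.
#' @param node a member of `ancestorSet(dag, root)`.
#' @param cfg a [SemanticConfig-class]; default decay 0.5.
#' @return a single contribution value in (0, 1].
#' @export
semanticContribution <- function(dag, root, node, cfg = semanticConfig()) {
  contribs <- .contributions(dag, root, cfg)
  if (!node %in% names(contribs))
    stop("node '", node, "' is not in the ancestor set of '", root, "'")
  unname(contribs[node])
}

#' Semantic value of a disease term
#'
#' The sum of the contributions of every term in the ancestor closure;
#' at least 1 (the self-contribution).
#'
#' @inheritParams semanticContribution
#' @param term the disease term.
#' @return a single value >= 1.
#' @export
semanticValue <- function(dag, term, cfg = semanticConfig()) {
  sum(.contributions(dag, term, cfg))
}

#' Disease semantic similarity from a DAG
#'
#' For each pair of diseases the shared-ancestor contributions are summed
#' from both sides and normalized by the two semantic values:
#' `S(i, j) = sum_{t in T(i) inters T(j)} (D1_i(t) + D1_j(t)) / (DV(i) + DV(j))`.
#' Diseases with disjoint ancestor closures score 0; the diagonal is
#' exactly 1.
#'
#' @param dag a [DiseaseDAG-class].
#' @param terms ordered identifiers to include (all in `dag`).
#' @param cfg a [SemanticConfig-class].
#' @return a [SimilarityMatrix-class] over `terms`.
#' @export
semanticSimilarity <- function(dag, terms = dag@terms, cfg = semanticConfig()) {
  if (!length(terms)) stop("empty term list")
  missing <- setdiff(terms, dag@terms)
  if (length(missing)) stop("unknown terms: ", paste(missing, collapse = ", "))
  contribs <- lapply(terms, .contributions, dag = dag, cfg = cfg)
  names(contribs) <- terms
  dv <- vapply(contribs, sum, numeric(1))
  n <- length(terms)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ci <- contribs[[i]]; cj <- contribs[[j]]
        shared <- intersect(names(ci), names(cj))
        s <- if (length(shared)) sum(ci[shared] + cj[shared]) / (dv[i] + dv[j]) else 0
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  dimnames(S) <- list(terms, terms)
  similarityMatrix(S)
}

#' Read a disease DAG from a child-parent edge list
#'
#' Two-column headerless TSV, `child<TAB>parent`, UTF-8; blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [DiseaseDAG-class].
#' @export
readDiseaseDAG <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(diseaseDAG())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed DAG line ", bad[1], ": expected child<TAB>parent")
  diseaseDAG(do.call(rbind, parts))
}
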