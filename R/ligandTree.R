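#' @include AllClasses.R AllGenerics.R
NULL

# Hydrogen-suppressed carbon skeletons of common phosphine substituents,
# relative to the attachment carbon (local id 1). Edge orders: 1 single,
# 1.5 aromatic, 2 double.
.substituents <- list(
  Me  = list(n = 1L, edges = NULL),
  Et  = list(n = 2L, edges = rbind(c(1, 2, 1))),
  nPr = list(n = 3L, edges = rbind(c(1, 2, 1), c(2, 3, 1))),
  iPr = list(n = 3L, edges = rbind(c(1, 2, 1), c(1, 3, 1))),
  nBu = list(n = 4L, edges = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  tBu = list(n = 4L, edges = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1))),
  # cyclohexyl: chair ring flattened to a 6-cycle
  Cy  = list(n = 6L, edges = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                                   c(4, 5, 1), c(5, 6, 1), c(6, 1, 1))),
  # benzyl: CH2 linker then an aromatic 6-ring
  Bn  = list(n = 7L, edges = rbind(c(1, 2, 1),
                                   c(2, 3, 1.5), c(3, 4, 1.5), c(4, 5, 1.5),
                                   c(5, 6, 1.5), c(6, 7, 1.5), c(7, 2, 1.5))),
  # 1-adamantyl: bridgehead attachment; 4 CH bridgeheads (1, 5, 6, 7),
  # 6 CH2 bridges (2, 3, 4, 8, 9, 10)
  Ad  = list(n = 10L, edges = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                                    c(2, 5, 1), c(3, 6, 1), c(4, 7, 1),
                                    c(5, 8, 1), c(8, 6, 1), c(6, 9, 1),
                                    c(9, 7, 1), c(7, 10, 1), c(10, 5, 1)))
)

#' Names of the bundled substituent skeletons
#'
#' @return character vector of substituent labels usable with
#'   [phosphineSpec()] and [buildTree()].
#' @export
substituentNames <- function() names(.substituents)

#' Assemble a tree-spec for a trialkyl/arylalkyl phosphine
#'
#' Builds the tree-spec record (the same structure serialized by
#' [writeTreeSpec()]) for `PR1R2R3` from three named substituents out of the
#' bundled skeleton library.
#'
#' @param name ligand label.
#' @param substituents character vector of exactly three names from
#'   [substituentNames()].
#' @return a tree-spec list with fields `name`, `root`, `nodes`, `edges`.
#' @examples
#' sp <- phosphineSpec("CyPtBu2", c("Cy", "tBu", "tBu"))
#' tr <- buildTree(sp)
#' @export
phosphineSpec <- function(name, substituents) {
  if (length(substituents) != 3L)
    stop("a phosphine has exactly three substituents on phosphorus")
  unknown <- setdiff(substituents, names(.substituents))
  if (length(unknown))
    stop(sprintf("unknown substituent(s): %s (available: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(.substituents), collapse = ", ")))
  nodes <- list(); edges <- list(); off <- 0L
  for (s in substituents) {
    sub <- .substituents[[s]]
    for (k in seq_len(sub$n))
      nodes[[length(nodes) + 1L]] <- list(id = off + k, element = "C")
    edges[[length(edges) + 1L]] <- list(i = "P", j = off + 1L, order = 1)
    if (!is.null(sub$edges))
      for (r in seq_len(nrow(sub$edges)))
        edges[[length(edges) + 1L]] <-
          list(i = off + sub$edges[r, 1], j = off + sub$edges[r, 2],
               order = sub$edges[r, 3])
    off <- off + sub$n
  }
  list(name = name, root = "P", nodes = nodes, edges = edges)
}

# adjacency list over internal ids (0 = root); returns list indexed by id + 1
.adjacency <- function(n, edges) {
  adj <- vector("list", n + 1L)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; o <- edges$order[r]
    adj[[i + 1L]] <- rbind(adj[[i + 1L]], c(j, o))
    adj[[j + 1L]] <- rbind(adj[[j + 1L]], c(i, o))
  }
  adj
}

# BFS bond distance from the phosphorus root
.bfsLayers <- function(n, adj) {
  layer <- rep(NA_integer_, n)
  frontier <- 0L; d <- 0L
  seen <- rep(FALSE, n + 1L); seen[1L] <- TRUE
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer()
    for (v in frontier) {
      nb <- adj[[v + 1L]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (!seen[w + 1L]) {
          seen[w + 1L] <- TRUE
          layer[w] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  layer
}

#' Build a ligand tree from a tree-spec or substituent list
#'
#' Assigns every carbon its layer (smallest bond count from the phosphorus
#' root) by breadth-first search; ring closures are retained as extra edges
#' and hydrogens never appear. The result is not yet canonical; see
#' [canonicalize()].
#'
#' @param spec either a tree-spec list (fields `name`, `root`, `nodes`,
#'   `edges`, as read by [readTreeSpec()]) or a character vector of three
#'   substituent names from [substituentNames()].
#' @param name ligand label, required when `spec` is a substituent vector;
#'   overrides the spec field when given.
#' @return a [LigandTree-class].
#' @examples
#' buildTree(c("nBu", "nBu", "nBu"), name = "PnBu3")
#' @export
buildTree <- function(spec, name = NULL) {
  if (is.character(spec))
    spec <- phosphineSpec(if (is.null(name)) paste(spec, collapse = "-")
                          else name, spec)
  if (!is.null(name)) spec$name <- name
  ids <- vapply(spec$nodes, function(x) as.integer(x$id), integer(1))
  elem <- vapply(spec$nodes, function(x) as.character(x$element), character(1))
  if (anyDuplicated(ids)) stop("structural error: duplicate node ids")
  if (!all(elem == "C"))
    stop(sprintf("unsupported element(s): %s (carbon-only substituents in v1)",
                 paste(unique(elem[elem != "C"]), collapse = ", ")))
  n <- length(ids)
  remap <- setNames(seq_len(n), as.character(ids))
  mapId <- function(x) {
    if (identical(x, "P") || identical(x, 0L) || identical(x, 0)) return(0L)
    v <- remap[as.character(as.integer(x))]
    if (is.na(v)) stop(sprintf("structural error: edge references unknown node %s", x))
    unname(v)
  }
  ed <- do.call(rbind, lapply(spec$edges, function(e)
    data.frame(i = mapId(e$i), j = mapId(e$j), order = as.numeric(e$order))))
  if (is.null(ed)) ed <- data.frame(i = integer(), j = integer(),
                                    order = numeric())
  if (nrow(ed) && !all(ed$order %in% c(1, 1.5, 2)))
    stop("structural error: bond orders must be 1, 1.5 or 2")
  adj <- .adjacency(n, ed)
  layer <- .bfsLayers(n, adj)
  if (anyNA(layer) && n > 0L)
    stop("structural error: spec is disconnected from the phosphorus root")
  nodes <- data.frame(id = seq_len(n), element = elem, layer = layer,
                      path = NA_character_, stringsAsFactors = FALSE)
  swap <- nrow(ed) > 0 & ed$i > ed$j & ed$j != 0L
  if (any(swap)) { tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp }
  # root edges stored as (0, j)
  rt <- ed$j == 0L
  if (any(rt)) { ed$j[rt] <- ed$i[rt]; ed$i[rt] <- 0L }
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  new("LigandTree", name = as.character(spec$name), nodes = nodes, edges = ed,
      canonical = FALSE)
}

# --- CIP-like hierarchical digraph comparison ---------------------------------
# The digraph is rooted at a child atom entered from its parent; children are
# all carbon neighbors except the parent, with ring closures to atoms already
# on the current path represented as terminal duplicate atoms. Priority
# comparison: higher bond order to the parent first, then the immediate
# substituent sphere (elementwise bond orders, then more substituents first),
# then recursion into the ordered subtrees. This diverges from strict CIP in
# that duplicated atoms compare equal to real terminal carbons; for the
# carbon-only ligands supported here the ordering is still unique wherever the
# encodings differ.

.mkdig <- function(node, parent, anc, adj) {
  nb <- adj[[node + 1L]]
  kids <- list()
  if (!is.null(nb)) {
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]; o <- nb[r, 2]
      if (w == parent || w == 0L) next
      if (w %in% anc) {
        kid <- list(order = o, kids = list())
      } else {
        kid <- .mkdig(w, node, c(anc, w), adj)
        kid$order <- o
      }
      kids[[length(kids) + 1L]] <- kid
    }
  }
  list(order = NA_real_, kids = .sortDigs(kids))
}

.digFrom <- function(child, parent, anc, adj, order) {
  d <- .mkdig(child, parent, c(anc, child), adj)
  d$order <- order
  d
}

# negative: a ranks before b (higher priority); 0: structurally identical
.cmpDig <- function(a, b) {
  if (!is.na(a$order) && !is.na(b$order) && a$order != b$order)
    return(if (a$order > b$order) -1L else 1L)
  na <- length(a$kids); nb <- length(b$kids)
  for (i in seq_len(min(na, nb))) {
    oa <- a$kids[[i]]$order; ob <- b$kids[[i]]$order
    if (oa != ob) return(if (oa > ob) -1L else 1L)
  }
  if (na != nb) return(if (na > nb) -1L else 1L)
  for (i in seq_len(na)) {
    d <- .cmpDig(a$kids[[i]], b$kids[[i]])
    if (d != 0L) return(d)
  }
  0L
}

# stable insertion sort by .cmpDig (ties keep input order)
.sortDigs <- function(digs) {
  k <- length(digs)
  if (k < 2L) return(digs)
  out <- digs[1L]
  for (i in 2:k) {
    pos <- length(out) + 1L
    for (j in seq_along(out)) {
      if (.cmpDig(digs[[i]], out[[j]]) < 0L) { pos <- j; break }
    }
    out <- append(out, digs[i], after = pos - 1L)
  }
  out
}

.sortIdxByDig <- function(digs) {
  k <- length(digs)
  idx <- seq_len(k)
  if (k < 2L) return(idx)
  for (i in 2:k) {
    key <- idx[i]
    j <- i - 1L
    while (j >= 1L && .cmpDig(digs[[key]], digs[[idx[j]]]) < 0L) {
      idx[j + 1L] <- idx[j]
      j <- j - 1L
    }
    idx[j + 1L] <- key
  }
  idx
}

.pathKey <- function(paths) {
  vapply(strsplit(paths, ".", fixed = TRUE), function(p)
    paste0(sprintf("%02d", length(p)),
           paste(sprintf("%03d", as.integer(p)), collapse = ".")),
    character(1))
}

#' @rdname canonicalize
setMethod("canonicalize", "LigandTree", function(tree) {
  n <- nrow(tree@nodes)
  if (n == 0L) {
    tree@canonical <- TRUE
    return(tree)
  }
  adj <- .adjacency(n, tree@edges)
  layer <- tree@nodes$layer
  maxL <- max(layer)
  path <- NULL
  # Pass 1 orders siblings by the CIP-like digraph comparison alone; later
  # passes additionally break structural ties by the canonical paths that
  # ring-closure edges point at (Morgan-style refinement), iterating until
  # the layout is stable. Without the refinement, structurally equivalent
  # siblings whose closures target different parts of the molecule (e.g. the
  # bridge methylenes of an adamantyl cage) would be ordered by input order,
  # breaking permutation invariance of the encoding.
  for (pass in 1:10) {
    prev <- path
    path <- rep(NA_character_, n)
    chain <- vector("list", n)
    profiles <- if (is.null(prev)) NULL else .closureProfiles(n, adj, layer, prev)
    orderGroup <- function(members, parent, parentChain, orders) {
      digs <- lapply(seq_along(members), function(k)
        .digFrom(members[k], parent, parentChain, adj, orders[k]))
      cmp <- function(a, b) {
        d <- .cmpDig(digs[[a]], digs[[b]])
        if (d != 0L || is.null(profiles)) return(d)
        .cmpProfile(profiles[[members[a]]], profiles[[members[b]]])
      }
      idx <- seq_along(members)
      if (length(idx) > 1L) for (i in 2:length(idx)) {
        key <- idx[i]
        j <- i - 1L
        while (j >= 1L && cmp(key, idx[j]) < 0L) {
          idx[j + 1L] <- idx[j]
          j <- j - 1L
        }
        idx[j + 1L] <- key
      }
      idx
    }
    l1 <- which(layer == 1L)
    ord <- orderGroup(l1, 0L, integer(), rep(1, length(l1)))
    for (r in seq_along(ord)) {
      v <- l1[ord[r]]
      path[v] <- as.character(r)
      chain[[v]] <- v
    }
    if (maxL > 1L) for (L in 2:maxL) {
      atL <- which(layer == L)
      parent <- integer(length(atL))
      for (k in seq_along(atL)) {
        v <- atL[k]
        nb <- adj[[v + 1L]]
        cand <- nb[nb[, 1] != 0L & layer[nb[, 1]] == L - 1L, 1]
        parent[k] <- if (length(cand) == 1L) cand
                     else cand[order(.pathKey(path[cand]))[1L]]
      }
      for (p in unique(parent)) {
        grp <- atL[parent == p]
        ords <- vapply(grp, function(v) {
          nb <- adj[[v + 1L]]
          nb[nb[, 1] == p, 2][1L]
        }, numeric(1))
        ord <- orderGroup(grp, p, chain[[p]], ords)
        for (r in seq_along(ord)) {
          v <- grp[ord[r]]
          path[v] <- paste(path[p], r, sep = ".")
          chain[[v]] <- c(chain[[p]], v)
        }
      }
    }
    if (!is.null(prev) && identical(prev, path)) break
  }
  slot <- order(.pathKey(path))
  newId <- integer(n); newId[slot] <- seq_len(n)
  nodes <- data.frame(id = seq_len(n), element = tree@nodes$element[slot],
                      layer = layer[slot], path = path[slot],
                      stringsAsFactors = FALSE)
  ed <- tree@edges
  nz <- ed$i != 0L
  ed$i[nz] <- newId[ed$i[nz]]
  ed$j <- newId[ed$j]
  swap <- ed$i > ed$j & ed$j != 0L
  if (any(swap)) { tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp }
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  new("LigandTree", name = tree@name, nodes = nodes, edges = ed,
      canonical = TRUE)
})

# Ring-closure profile per node under a given path assignment: for every
# non-tree edge touching the node's subtree, a token pairing the inside
# endpoint's subtree-relative path with the absolute (outside) or relative
# (inside) path of the far endpoint. Sorted tokens; compared elementwise.
.closureProfiles <- function(n, adj, layer, path) {
  key <- .pathKey(path)
  parentOf <- integer(n)
  for (v in seq_len(n)) {
    if (layer[v] == 1L) { parentOf[v] <- 0L; next }
    nb <- adj[[v + 1L]]
    cand <- nb[nb[, 1] != 0L & layer[nb[, 1]] == layer[v] - 1L, 1]
    parentOf[v] <- if (length(cand) == 1L) cand
                   else cand[order(key[cand])[1L]]
  }
  closures <- list()
  for (v in seq_len(n)) {
    nb <- adj[[v + 1L]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (w == 0L || w < v) next
      if (parentOf[w] == v || parentOf[v] == w) next
      closures[[length(closures) + 1L]] <- c(v, w)
    }
  }
  rel <- function(x, v) {
    # path of x relative to subtree root v ("" when x == v)
    if (x == v) return("")
    sub("^\\.", "", substring(path[x], nchar(path[v]) + 1L))
  }
  inSub <- function(x, v) x == v || startsWith(path[x], paste0(path[v], "."))
  lapply(seq_len(n), function(v) {
    toks <- character()
    for (cl in closures) {
      a <- cl[1]; b <- cl[2]
      ia <- inSub(a, v); ib <- inSub(b, v)
      if (!ia && !ib) next
      if (ia && ib) {
        toks <- c(toks, paste0("i:", .pathKey(rel(a, v)), ">i:",
                               .pathKey(rel(b, v))))
      } else {
        ins <- if (ia) a else b
        out <- if (ia) b else a
        toks <- c(toks, paste0("i:", .pathKey(rel(ins, v)), ">o:", key[out]))
      }
    }
    sort(toks)
  })
}

.cmpProfile <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  0L
}

#' Build the slot template spanning a ligand set
#'
#' The template is the per-position maximum branching pattern over the set:
#' the union of all canonical node paths, ordered layer-major then
#' priority-minor. Adding a tree that already fits leaves the template
#' unchanged. The template is typically built once from the training ligands
#' and frozen; encoding a bulkier unseen ligand later raises a capacity error
#' rather than silently truncating.
#'
#' @param trees list of [LigandTree-class] objects (canonicalized on the fly
#'   when necessary).
#' @return a [GraphTemplate-class].
#' @examples
#' tpl <- buildTemplate(list(buildTree(c("Me", "Me", "Me"), "PMe3"),
#'                           buildTree(c("Et", "Et", "Et"), "PEt3")))
#' totalSlots(tpl)   # 6
#' @export
buildTemplate <- function(trees) {
  if (!length(trees)) stop("cannot build a template from an empty ligand set")
  paths <- unique(unlist(lapply(trees, function(tr) {
    if (!is(tr, "LigandTree")) stop("trees must be LigandTree objects")
    if (!tr@canonical) tr <- canonicalize(tr)
    tr@nodes$path
  })))
  new("GraphTemplate", paths = paths[order(.pathKey(paths))])
}

#' Encode a ligand tree as an aligned graph
#'
#' Maps the canonical tree into the fixed slot layout: occupied slots get
#' presence 1, vacant slots 0 and carry no edges; bond orders are written into
#' the symmetric edge matrix over the root plus all slots.
#'
#' @param tree a [LigandTree-class]; canonicalized automatically if needed.
#' @param template a [GraphTemplate-class] the tree must fit into.
#' @return an [AlignedGraph-class].
#' @examples
#' tpl <- buildTemplate(list(buildTree(c("Et", "Et", "Et"), "PEt3")))
#' encodeGraph(buildTree(c("Me", "Me", "Me"), "PMe3"), tpl)
#' @export
encodeGraph <- function(tree, template) {
  if (!tree@canonical) tree <- canonicalize(tree)
  idx <- match(tree@nodes$path, template@paths)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf(
      "capacity error: ligand '%s' exceeds the template at layer %d (path %s)",
      tree@name, tree@nodes$layer[bad], tree@nodes$path[bad]))
  }
  n <- length(template@paths)
  presence <- numeric(n)
  presence[idx] <- 1
  E <- matrix(0, n + 1L, n + 1L)
  mapTo <- function(id) if (id == 0L) 1L else idx[id] + 1L
  ed <- tree@edges
  for (r in seq_len(nrow(ed))) {
    a <- mapTo(ed$i[r]); b <- mapTo(ed$j[r])
    E[a, b] <- ed$order[r]; E[b, a] <- ed$order[r]
  }
  dimnames(E) <- list(c("P", template@paths), c("P", template@paths))
  new("AlignedGraph", ligand = tree@name, presence = presence, edgeOrder = E)
}

#' Decode an aligned graph back into a ligand tree
#'
#' Inverse of [encodeGraph()] up to graph isomorphism: present slots become
#' nodes, matrix entries become edges, layers are recomputed from scratch.
#'
#' @param graph an [AlignedGraph-class].
#' @param template the [GraphTemplate-class] it was encoded against.
#' @return a [LigandTree-class].
#' @export
decodeGraph <- function(graph, template) {
  stopifnot(length(graph@presence) == length(template@paths))
  present <- which(graph@presence == 1)
  nodes <- lapply(seq_along(present), function(k)
    list(id = k, element = "C"))
  remap <- setNames(seq_along(present), as.character(present))
  E <- graph@edgeOrder
  edges <- list()
  for (a in seq_len(nrow(E))) for (b in seq_len(ncol(E))) {
    if (b <= a || E[a, b] == 0) next
    toId <- function(z) if (z == 1L) "P" else unname(remap[as.character(z - 1L)])
    edges[[length(edges) + 1L]] <- list(i = toId(a), j = toId(b),
                                        order = E[a, b])
  }
  buildTree(list(name = graph@ligand, root = "P", nodes = nodes,
                 edges = edges))
}

#' Read a tree-spec JSON file
#'
#' Format: `{"name": str, "root": "P", "nodes": [{"id": int, "element":
#' "C"}], "edges": [{"i": "P"|int, "j": int, "order": 1|1.5|2}]}`. Layers are
#' always computed, never read.
#'
#' @param path JSON file path.
#' @return a [LigandTree-class].
#' @export
readTreeSpec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  buildTree(spec)
}

#' Write a ligand tree as a tree-spec JSON file
#'
#' @param tree a [LigandTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTreeSpec <- function(tree, path) {
  spec <- list(
    name = tree@name, root = "P",
    nodes = lapply(seq_len(nrow(tree@nodes)), function(k)
      list(id = tree@nodes$id[k], element = tree@nodes$element[k])),
    edges = lapply(seq_len(nrow(tree@edges)), function(r)
      list(i = if (tree@edges$i[r] == 0L) "P" else tree@edges$i[r],
           j = tree@edges$j[r], order = tree@edges$order[r])))
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Bundled ligand fixtures
#'
#' Reads the tree-spec files shipped with the package for the phosphines named
#' in the source dataset (e.g. tri-n-butylphosphine, tricyclohexylphosphine,
#' di(1-adamantyl)benzylphosphine).
#'
#' @param names optional subset of fixture names (file base names).
#' @return named list of [LigandTree-class] objects.
#' @examples
#' trees <- ligandFixtures()
#' vapply(trees, stericProxy, integer(1))
#' @export
ligandFixtures <- function(names = NULL) {
  dir <- system.file("extdata", "ligands", package = "TreeMPNN")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  base <- sub("\\.json$", "", basename(files))
  if (!is.null(names)) {
    miss <- setdiff(names, base)
    if (length(miss))
      stop(sprintf("no fixture for: %s", paste(miss, collapse = ", ")))
    files <- files[match(names, base)]; base <- names
  }
  setNames(lapply(files, readTreeSpec), base)
}
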