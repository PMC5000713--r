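# Generic gating engine: geometric gates evaluated in display (transformed)
# space, Boolean gates over other gates, and hierarchical gate trees that
# emit per-population statistics. Boundary convention is half-open [lo, hi)
# everywhere so that adjacent regions (quadrant cells, hi/lo splits) are
# disjoint and partition their parent exactly.

#' Geometric gate constructors
#'
#' Four gate geometries, all evaluated in display space (after the
#' per-channel transform):
#'
#' * `gate_threshold(channel, lo, hi)` - one channel, `lo <= x < hi`;
#' * `gate_rectangle(xchannel, ychannel, xlim, ylim)` - two channels,
#'   half-open box;
#' * `gate_quadrant(xchannel, ychannel, xsplit, ysplit, cell)` - one of the
#'   four cells of a quadrant split, `cell` one of `"++", "+-", "-+", "--"`
#'   (x sign first; `+` means at or above the split);
#' * `gate_polygon(xchannel, ychannel, xs, ys)` - simple polygon.
#'
#' Channels may be raw column names (`"SSC"`) or marker names resolved
#' through the event table's channel map (`"CD3"`).
#'
#' @param channel,xchannel,ychannel channel or marker reference.
#' @param lo,hi threshold bounds (display units), either may be infinite.
#' @param xlim,ylim numeric length-2 half-open bounds.
#' @param xsplit,ysplit quadrant split coordinates.
#' @param cell quadrant cell selector.
#' @param xs,ys polygon vertex coordinates (not self-intersecting).
#' @return list of class `gate_geometry`.
#' @name gate-geometry
NULL

#' @rdname gate-geometry
#' @export
gate_threshold <- function(channel, lo = -Inf, hi = Inf) {
  stopifnot(lo < hi)
  structure(list(kind = "threshold", channels = channel, lo = lo, hi = hi),
            class = "gate_geometry")
}

#' @rdname gate-geometry
#' @export
gate_rectangle <- function(xchannel, ychannel, xlim, ylim) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L,
            xlim[1] < xlim[2], ylim[1] < ylim[2])
  structure(list(kind = "rectangle", channels = c(xchannel, ychannel),
                 xlim = xlim, ylim = ylim),
            class = "gate_geometry")
}

#' @rdname gate-geometry
#' @export
gate_quadrant <- function(xchannel, ychannel, xsplit, ysplit,
                          cell = c("++", "+-", "-+", "--")) {
  cell <- match.arg(cell)
  stopifnot(is.finite(xsplit), is.finite(ysplit))
  structure(list(kind = "quadrant", channels = c(xchannel, ychannel),
                 xsplit = xsplit, ysplit = ysplit, cell = cell),
            class = "gate_geometry")
}

#' @rdname gate-geometry
#' @export
gate_polygon <- function(xchannel, ychannel, xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L,
            all(is.finite(xs)), all(is.finite(ys)))
  structure(list(kind = "polygon", channels = c(xchannel, ychannel),
                 xs = xs, ys = ys),
            class = "gate_geometry")
}

# Apply the per-channel display transform. `transforms` maps channel (or
# marker) references to either the string "linear" or a logicle_params
# object; unlisted channels default to linear (identity).
display_values <- function(table, ref, transforms) {
  col <- resolve_channel(table, ref)
  x <- table[[col]]
  tr <- transforms[[ref]]
  if (is.null(tr)) tr <- transforms[[col]]
  if (is.null(tr) || identical(tr, "linear")) return(x)
  if (inherits(tr, "logicle_params")) return(to_logicle(x, tr))
  stop("unknown transform for channel ", ref)
}

#' Evaluate a geometric gate
#'
#' @param table an [event_table()].
#' @param gate a gate built by one of the [gate-geometry] constructors.
#' @param transforms named list mapping channel/marker references to
#'   `"linear"` or a [logicle_params()] object; unlisted channels are linear.
#' @return logical event mask.
#' @export
eval_geometric_gate <- function(table, gate, transforms = list()) {
  stopifnot(inherits(gate, "gate_geometry"))
  if (nrow(table) == 0L) return(logical(0))
  x <- display_values(table, gate$channels[1], transforms)
  switch(gate$kind,
    threshold = x >= gate$lo & x < gate$hi,
    rectangle = {
      y <- display_values(table, gate$channels[2], transforms)
      x >= gate$xlim[1] & x < gate$xlim[2] & y >= gate$ylim[1] & y < gate$ylim[2]
    },
    quadrant = {
      y <- display_values(table, gate$channels[2], transforms)
      xp <- x >= gate$xsplit
      yp <- y >= gate$ysplit
      switch(gate$cell,
             "++" = xp & yp, "+-" = xp & !yp, "-+" = !xp & yp, "--" = !xp & !yp)
    },
    polygon = {
      y <- display_values(table, gate$channels[2], transforms)
      as.logical(mgcv::in.out(cbind(c(gate$xs, gate$xs[1]), c(gate$ys, gate$ys[1])),
                              cbind(x, y)))
    },
    stop("unknown gate kind: ", gate$kind))
}

#' Boolean gate expressions
#'
#' Expression trees over gate identifiers with `AND`, `OR`, `NOT`.
#' A bare character string is a reference to a named gate; `bool_and()`,
#' `bool_or()` and `bool_not()` combine references or sub-expressions.
#' Unions evaluate set-wise, so an event belonging to several operands is
#' counted once — the convention used for pooling NKT membership gates
#' without double counting.
#'
#' @param ... sub-expressions or gate-id strings.
#' @param x sub-expression or gate-id string.
#' @return list of class `bool_expr` (or a bare string reference).
#' @name bool-expr
NULL

#' @rdname bool-expr
#' @export
bool_and <- function(...) structure(list(op = "and", args = list(...)), class = "bool_expr")

#' @rdname bool-expr
#' @export
bool_or <- function(...) structure(list(op = "or", args = list(...)), class = "bool_expr")

#' @rdname bool-expr
#' @export
bool_not <- function(x) structure(list(op = "not", args = list(x)), class = "bool_expr")

#' Evaluate a Boolean gate expression
#'
#' @param expr a [bool-expr] tree or a gate-id string.
#' @param masks named list of logical masks of equal length, one per gate id.
#' @return logical event mask.
#' @export
eval_boolean <- function(expr, masks) {
  lens <- unique(vapply(masks, length, 0L))
  if (length(lens) > 1L) stop("masks must all have equal length")
  rec <- function(e) {
    if (is.character(e)) {
      if (!e %in% names(masks)) stop("unresolved gate id: ", e)
      return(masks[[e]])
    }
    stopifnot(inherits(e, "bool_expr"))
    vals <- lapply(e$args, rec)
    switch(e$op,
           and = Reduce(`&`, vals),
           or = Reduce(`|`, vals),
           not = !vals[[1]],
           stop("unknown Boolean operator: ", e$op))
  }
  rec(expr)
}

# Gate ids referenced anywhere inside a Boolean expression.
bool_refs <- function(expr) {
  if (is.character(expr)) return(expr)
  unique(unlist(lapply(expr$args, bool_refs)))
}

#' Build a gate tree
#'
#' A gate tree is a hierarchy of nodes below an implicit `root` (the
#' quality-controlled All Cells population). Each node holds either a
#' geometric gate or a Boolean expression over other node ids; a node's
#' event mask is always intersected with its parent's.
#'
#' @param nodes list of nodes built with [gate_node()].
#' @return list of class `gate_tree`, with nodes in topological order.
#' @export
gate_tree <- function(nodes) {
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("schema error: duplicate node ids")
  names(nodes) <- ids
  deps <- lapply(nodes, function(nd) {
    d <- if (nd$parent == "root") character() else nd$parent
    if (!is.null(nd$boolean)) d <- c(d, bool_refs(nd$boolean))
    d
  })
  for (id in ids) {
    miss <- setdiff(deps[[id]], ids)
    if (length(miss) > 0L)
      stop("schema error: node ", id, " references unknown node(s): ",
           paste(miss, collapse = ", "))
  }
  # Kahn topological sort; cycles leave nodes unplaced
  placed <- character()
  order <- character()
  remaining <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining,
                              function(id) all(deps[[id]] %in% placed), TRUE)]
    if (length(ready) == 0L)
      stop("schema error: cycle or orphan among nodes: ",
           paste(remaining, collapse = ", "))
    placed <- c(placed, ready)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(nodes = nodes[order]), class = "gate_tree")
}

#' @rdname gate_tree
#' @param id unique node identifier.
#' @param parent parent node id, or `"root"`.
#' @param gate a [gate-geometry] gate (exclusive with `boolean`).
#' @param boolean a [bool-expr] expression over node ids (exclusive with
#'   `gate`).
#' @param name display name; defaults to `id`.
#' @param report whether the node is a reported population.
#' @param major id of the node's major-cell-type ancestor (used for
#'   percent-of-major and for anchoring absolute counts); `NA` for nodes at
#'   or above major level.
#' @param link cross-panel link id: nodes sharing a link id are required to
#'   carry identical geometry in every panel using them.
#' @export
gate_node <- function(id, parent, gate = NULL, boolean = NULL, name = id,
                      report = FALSE, major = NA_character_,
                      link = NA_character_) {
  if (is.null(gate) == is.null(boolean))
    stop("node ", id, " needs exactly one of gate= or boolean=")
  list(id = id, parent = parent, gate = gate, boolean = boolean, name = name,
       report = report, major = major, link = link)
}

#' Apply a gate tree to an event table
#'
#' Evaluates every node in topological order on the events selected by
#' `root_mask` (normally the combined QC mask), intersecting each node's
#' gate with its parent's mask, and returns per-node population statistics.
#'
#' @param table an [event_table()].
#' @param tree a [gate_tree()].
#' @param transforms per-channel display transforms (see
#'   [eval_geometric_gate()]).
#' @param root_mask logical mask of root (All Cells) events; default all.
#' @param only_reported drop non-report nodes from the result.
#' @return a data.frame of population statistics: `population`, `node`,
#'   `parent`, `major`, `n_events`, `pct_parent`, `pct_major`, `pct_all`,
#'   `abs_per_ul` (`NA` until filled by [propagate_absolute()]) and `valid`
#'   (`FALSE` when fewer than 100 events). The per-node masks are attached
#'   as attribute `"masks"`.
#' @export
apply_gate_tree <- function(table, tree, transforms = list(),
                            root_mask = rep(TRUE, nrow(table)),
                            only_reported = FALSE) {
  stopifnot(inherits(tree, "gate_tree"))
  masks <- list(root = root_mask)
  for (nd in tree$nodes) {
    parent_mask <- masks[[nd$parent]]
    m <- if (!is.null(nd$gate)) {
      eval_geometric_gate(table, nd$gate, transforms) & parent_mask
    } else {
      eval_boolean(nd$boolean, masks) & parent_mask
    }
    masks[[nd$id]] <- m
  }
  n_root <- sum(root_mask)
  rows <- lapply(tree$nodes, function(nd) {
    k <- sum(masks[[nd$id]])
    kp <- sum(masks[[nd$parent]])
    km <- if (!is.na(nd$major) && nd$major %in% names(masks))
      sum(masks[[nd$major]]) else NA_integer_
    data.frame(population = nd$name, node = nd$id, parent = nd$parent,
               major = nd$major, n_events = k,
               pct_parent = if (kp > 0) 100 * k / kp else NA_real_,
               pct_major = if (!is.na(km) && km > 0) 100 * k / km else NA_real_,
               pct_all = if (n_root > 0) 100 * k / n_root else NA_real_,
               abs_per_ul = NA_real_,
               valid = k >= 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (only_reported) {
    keep <- vapply(tree$nodes, `[[`, TRUE, "report")
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "masks") <- masks
  out
}
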