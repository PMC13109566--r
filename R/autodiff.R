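# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every layer in the segmentation network is a composition of a dozen
# primitives (dense matmul, bias add, ReLU, row gather, constant sparse
# aggregation, grouped softmax/max, ...). Each primitive below accepts
# either a plain matrix or a tape node ("ad" object) and routes
# accordingly, so the very same layer code runs in inference mode (plain
# matrices, no tape) and in training mode (gradients recorded).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

is_ad <- function(x) inherits(x, "ad")

ad_node <- function(tape, val, parents = integer(0), backward = NULL,
                    param = NA_character_) {
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$nodes[[id]] <- list(val = val, parents = parents, backward = backward,
                           param = param)
  structure(list(tape = tape, id = id), class = "ad")
}

ad_val <- function(x) if (is_ad(x)) x$tape$nodes[[x$id]]$val else x

# constants enter the tape lazily: plain matrices stay plain until they
# meet a node, so pure-inference calls never build a tape at all
ad_lift <- function(tape, x) if (is_ad(x)) x else ad_node(tape, x)

ad_param <- function(tape, val, name) ad_node(tape, val, param = name)

# Backward pass from a scalar node; returns named list of parameter grads.
ad_backward <- function(loss) {
  tape <- loss$tape
  n <- tape$n
  grads <- vector("list", n)
  grads[[loss$id]] <- matrix(1, 1, 1)
  param_grads <- list()
  for (id in rev(seq_len(n))) {
    node <- tape$nodes[[id]]
    g <- grads[[id]]
    if (is.null(g)) next
    if (!is.na(node$param)) {
      param_grads[[node$param]] <-
        if (is.null(param_grads[[node$param]])) g else param_grads[[node$param]] + g
      next
    }
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (!is.null(pg[[k]])) {
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
    grads[[id]] <- NULL   # free memory as we go
  }
  param_grads
}

# binary-op helper: pick the tape if either argument carries one
tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  NULL
}

.mm <- function(x, w) {
  tp <- tape_of(x, w)
  if (is.null(tp)) return(x %*% w)
  x <- ad_lift(tp, x); w <- ad_lift(tp, w)
  xv <- ad_val(x); wv <- ad_val(w)
  ad_node(tp, xv %*% wv, c(x$id, w$id),
          function(g) list(g %*% t(wv), crossprod(xv, g)))
}

# add a 1 x C bias row to every row of x
.bias <- function(x, b) {
  tp <- tape_of(x, b)
  if (is.null(tp)) return(sweep(x, 2, as.vector(b), `+`))
  x <- ad_lift(tp, x); b <- ad_lift(tp, b)
  xv <- ad_val(x)
  ad_node(tp, sweep(xv, 2, as.vector(ad_val(b)), `+`), c(x$id, b$id),
          function(g) list(g, matrix(colSums(g), 1)))
}

.add <- function(x, y) {
  tp <- tape_of(x, y)
  if (is.null(tp)) return(x + y)
  x <- ad_lift(tp, x); y <- ad_lift(tp, y)
  ad_node(tp, ad_val(x) + ad_val(y), c(x$id, y$id), function(g) list(g, g))
}

.sub <- function(x, y) {
  tp <- tape_of(x, y)
  if (is.null(tp)) return(x - y)
  x <- ad_lift(tp, x); y <- ad_lift(tp, y)
  ad_node(tp, ad_val(x) - ad_val(y), c(x$id, y$id), function(g) list(g, -g))
}

.relu <- function(x) {
  if (!is_ad(x)) return(pmax(x, 0))
  xv <- ad_val(x)
  mask <- xv > 0
  ad_node(x$tape, xv * mask, x$id, function(g) list(g * mask))
}

.cbind <- function(...) {
  xs <- list(...)
  tp <- do.call(tape_of, xs)
  if (is.null(tp)) return(do.call(cbind, xs))
  xs <- lapply(xs, ad_lift, tape = tp)
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ad_node(tp, do.call(cbind, vals), vapply(xs, function(x) x$id, integer(1)),
          function(g) lapply(seq_along(widths),
                             function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

.gather <- function(x, idx) {
  if (!is_ad(x)) return(x[idx, , drop = FALSE])
  xv <- ad_val(x)
  nr <- nrow(xv)
  ad_node(x$tape, xv[idx, , drop = FALSE], x$id, function(g) {
    rs <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# fixed sparse aggregation: A (G x P, constant weights) %*% x
.spmm <- function(A, x) {
  if (!is_ad(x)) return(as.matrix(A %*% x))
  xv <- ad_val(x)
  At <- Matrix::t(A)
  ad_node(x$tape, as.matrix(A %*% xv), x$id,
          function(g) list(as.matrix(At %*% g)))
}

# scale each row of x by the matching entry of column vector w (P x 1)
.rowscale <- function(x, w) {
  tp <- tape_of(x, w)
  if (is.null(tp)) return(x * as.vector(w))
  x <- ad_lift(tp, x); w <- ad_lift(tp, w)
  xv <- ad_val(x); wv <- as.vector(ad_val(w))
  ad_node(tp, xv * wv, c(x$id, w$id),
          function(g) list(g * wv, matrix(rowSums(g * xv), ncol = 1)))
}

# per-row dot product of two equal-shape matrices -> P x 1
.rowdot <- function(x, y) {
  tp <- tape_of(x, y)
  if (is.null(tp)) return(matrix(rowSums(x * y), ncol = 1))
  x <- ad_lift(tp, x); y <- ad_lift(tp, y)
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(tp, matrix(rowSums(xv * yv), ncol = 1), c(x$id, y$id),
          function(g) {
            gv <- as.vector(g)
            list(yv * gv, xv * gv)
          })
}

# softmax of a column of logits within groups (P x 1 -> P x 1)
.group_softmax <- function(logits, group) {
  compute <- function(lv) {
    mx <- stats::ave(lv, group, FUN = max)
    e <- exp(lv - mx)
    s <- stats::ave(e, group, FUN = sum)
    e / s
  }
  if (!is_ad(logits)) return(matrix(compute(as.vector(logits)), ncol = 1))
  lv <- as.vector(ad_val(logits))
  w <- compute(lv)
  ad_node(logits$tape, matrix(w, ncol = 1), logits$id, function(g) {
    gv <- as.vector(g)
    s <- stats::ave(w * gv, group, FUN = sum)
    list(matrix(w * (gv - s), ncol = 1))
  })
}

# channel-wise max over row groups; `rows` is a list mapping each output
# row to its input rows (precomputed, constant per cloud)
.group_max <- function(x, rows) {
  maxpool <- function(xv) {
    G <- length(rows)
    C <- ncol(xv)
    out <- matrix(0, G, C)
    arg <- matrix(0L, G, C)
    for (g in seq_len(G)) {
      sub <- xv[rows[[g]], , drop = FALSE]
      j <- max.col(t(sub), ties.method = "first")
      arg[g, ] <- rows[[g]][j]
      out[g, ] <- sub[cbind(j, seq_len(C))]
    }
    list(out = out, arg = arg)
  }
  if (!is_ad(x)) return(maxpool(x)$out)
  xv <- ad_val(x)
  mp <- maxpool(xv)
  ad_node(x$tape, mp$out, x$id, function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    C <- ncol(xv)
    for (col in seq_len(C)) {
      idx <- mp$arg[, col]
      gcol <- g[, col]
      acc <- rowsum(gcol, group = idx)
      out[as.integer(rownames(acc)), col] <-
        out[as.integer(rownames(acc)), col] + acc
    }
    list(out)
  })
}

# weighted cross-entropy over per-point class scores (terminal loss node);
# labels are 0-based class ids, weights one value per class
.ce_loss <- function(scores, labels, class_weights) {
  sv <- ad_val(scores)
  n <- nrow(sv)
  mx <- apply(sv, 1, max)
  e <- exp(sv - mx)
  p <- e / rowSums(e)
  wi <- class_weights[labels + 1L]
  picked <- p[cbind(seq_len(n), labels + 1L)]
  loss <- sum(-wi * log(pmax(picked, 1e-12))) / sum(wi)
  if (!is_ad(scores)) return(loss)
  onehot <- matrix(0, n, ncol(sv))
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  dscores <- (p - onehot) * wi / sum(wi)
  ad_node(scores$tape, matrix(loss, 1, 1), scores$id,
          function(g) list(dscores * as.vector(g)))
}

# linear layer helper used throughout the network: x %*% W + b
.linear <- function(x, W, b = NULL) {
  out <- .mm(x, W)
  if (!is.null(b)) out <- .bias(out, b)
  out
}
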