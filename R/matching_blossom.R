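# Maximum-weight matching on a general weighted graph by the primal-dual
# blossom method (Edmonds' blossom shrinking with Galil's O(n^3)
# bookkeeping).  Vertices are 1..n; blossoms get ids above n and are
# recycled.  Dual variables are stored doubled so integer weights stay
# integer.  Used as the final fallback of the stepwise pair-matching
# procedure and exposed through max_weight_pairs().

# W: symmetric non-negative weight matrix, zero diagonal; entries > 0 are
# edges.  Returns integer mate vector (0 = unmatched).
blossom_mates <- function(W) {
  n <- nrow(W)
  if (n == 0L) return(integer(0))
  nbr <- lapply(seq_len(n), function(v) which(W[v, ] > 0 & seq_len(n) != v))
  maxweight <- max(W, 0)
  if (maxweight <= 0) return(rep(0L, n))
  cap <- 2L * n + 2L

  mate <- rep(0L, n)
  label <- rep(0L, cap)                 # 0 free, 1 S, 2 T (+4 breadcrumb)
  le_v <- rep(0L, cap); le_w <- rep(0L, cap)   # label edge (v, w), w inside
  le_none <- rep(TRUE, cap)
  inblossom <- seq_len(n)
  parent <- rep(0L, cap)
  bbase <- rep(0L, cap); bbase[seq_len(n)] <- seq_len(n)
  childs <- vector("list", cap)         # ordered sub-blossom ids
  bedges <- vector("list", cap)         # connecting (v, w) pairs
  mybest <- vector("list", cap)         # least-slack edges to S-blossoms
  bestedge <- vector("list", cap)       # c(v, w) or NULL
  dualvar <- rep(maxweight, n)          # 2 * u(v)
  bldual <- rep(NA_real_, cap)          # z(b); NA = blossom inactive
  freeb <- rev(seq.int(n + 1L, cap))
  allowed <- matrix(FALSE, n, n)
  queue <- integer(0)

  slack <- function(v, w) dualvar[v] + dualvar[w] - 2 * W[v, w]

  leaves <- function(b) {
    if (b <= n) return(b)
    out <- integer(0)
    stack <- childs[[b]]
    while (length(stack)) {
      t <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (t <= n) out <- c(out, t) else stack <- c(stack, childs[[t]])
    }
    out
  }

  assign_label <- function(w, t, v) {
    b <- inblossom[w]
    label[w] <<- t; label[b] <<- t
    if (v != 0L) {
      le_v[w] <<- v; le_w[w] <<- w; le_none[w] <<- FALSE
      le_v[b] <<- v; le_w[b] <<- w; le_none[b] <<- FALSE
    } else {
      le_none[w] <<- TRUE; le_none[b] <<- TRUE
    }
    bestedge[w] <<- list(NULL)
    bestedge[b] <<- list(NULL)
    if (t == 1L) {
      queue <<- c(queue, leaves(b))
    } else {
      bs <- bbase[b]
      assign_label(mate[bs], 1L, bs)
    }
  }

  # Trace back from v and w; return base vertex of a new blossom or 0 when
  # an augmenting path has been found.
  scan_blossom <- function(v, w) {
    path <- integer(0)
    bse <- 0L
    while (v != 0L) {
      b <- inblossom[v]
      if (bitwAnd(label[b], 4L) > 0L) { bse <- bbase[b]; break }
      path <- c(path, b)
      label[b] <<- 5L
      if (le_none[b]) {
        v <- 0L
      } else {
        v <- le_v[b]
        b <- inblossom[v]
        v <- le_v[b]
      }
      if (w != 0L) { tmp <- v; v <- w; w <- tmp }
    }
    if (length(path)) label[path] <<- 1L
    bse
  }

  add_blossom <- function(bse, v, w) {
    bb <- inblossom[bse]; bv <- inblossom[v]; bw <- inblossom[w]
    b <- freeb[length(freeb)]; freeb <<- freeb[-length(freeb)]
    bbase[b] <<- bse; parent[b] <<- 0L; parent[bb] <<- b
    path <- integer(0)
    edgs <- list(c(v, w))
    while (bv != bb) {
      parent[bv] <<- b
      path <- c(path, bv)
      edgs <- c(edgs, list(c(le_v[bv], le_w[bv])))
      v <- le_v[bv]
      bv <- inblossom[v]
    }
    path <- rev(c(path, bb))
    edgs <- rev(edgs)
    while (bw != bb) {
      parent[bw] <<- b
      path <- c(path, bw)
      edgs <- c(edgs, list(c(le_w[bw], le_v[bw])))
      w <- le_v[bw]
      bw <- inblossom[w]
    }
    childs[[b]] <<- path
    bedges[[b]] <<- edgs
    label[b] <<- 1L
    le_v[b] <<- le_v[bb]; le_w[b] <<- le_w[bb]; le_none[b] <<- le_none[bb]
    bldual[b] <<- 0
    for (lv in leaves(b)) {
      if (label[inblossom[lv]] == 2L) queue <<- c(queue, lv)
      inblossom[lv] <<- b
    }
    # Least-slack edges from the new blossom to other S-blossoms.
    bestedgeto <- vector("list", cap)
    for (bv2 in path) {
      if (bv2 > n) {
        if (!is.null(mybest[[bv2]])) {
          nblist <- mybest[[bv2]]
          mybest[bv2] <<- list(NULL)
        } else {
          lv <- leaves(bv2)
          nblist <- do.call(rbind, lapply(lv, function(x)
            if (length(nbr[[x]])) cbind(x, nbr[[x]]) else NULL))
        }
      } else {
        nblist <- if (length(nbr[[bv2]])) cbind(bv2, nbr[[bv2]]) else NULL
      }
      if (!is.null(nblist) && nrow(nblist)) {
        for (r in seq_len(nrow(nblist))) {
          i <- nblist[r, 1L]; j <- nblist[r, 2L]
          if (inblossom[j] == b) { tmp <- i; i <- j; j <- tmp }
          bj <- inblossom[j]
          if (bj != b && label[bj] == 1L) {
            cur <- bestedgeto[[bj]]
            if (is.null(cur) || slack(i, j) < slack(cur[1L], cur[2L]))
              bestedgeto[[bj]] <- c(i, j)
          }
        }
      }
      bestedge[bv2] <<- list(NULL)
    }
    kept <- Filter(Negate(is.null), bestedgeto)
    mybest[[b]] <<- if (length(kept)) do.call(rbind, kept) else NULL
    be <- NULL; bs <- Inf
    if (!is.null(mybest[[b]])) {
      for (r in seq_len(nrow(mybest[[b]]))) {
        k <- mybest[[b]][r, ]
        ks <- slack(k[1L], k[2L])
        if (ks < bs) { bs <- ks; be <- k }
      }
    }
    bestedge[b] <<- list(be)
  }

  expand_blossom <- function(b, endstage) {
    for (s in childs[[b]]) {
      parent[s] <<- 0L
      if (s <= n) {
        inblossom[s] <<- s
      } else if (endstage && bldual[s] == 0) {
        expand_blossom(s, endstage)
      } else {
        for (lv in leaves(s)) inblossom[lv] <<- s
      }
    }
    if (!endstage && label[b] == 2L) {
      entrychild <- inblossom[le_w[b]]
      cs <- childs[[b]]
      len <- length(cs)
      wrap <- function(idx) (idx %% len) + 1L
      j <- which(cs == entrychild)[1L] - 1L
      jstep <- if (bitwAnd(j, 1L) > 0L) { j <- j - len; 1L } else -1L
      v <- le_v[b]; w <- le_w[b]
      while (j != 0L) {
        if (jstep == 1L) {
          pq <- bedges[[b]][[wrap(j)]]; p <- pq[1L]; q <- pq[2L]
        } else {
          qp <- bedges[[b]][[wrap(j - 1L)]]; q <- qp[1L]; p <- qp[2L]
        }
        label[w] <<- 0L
        label[q] <<- 0L
        assign_label(w, 2L, v)
        allowed[p, q] <<- TRUE; allowed[q, p] <<- TRUE
        j <- j + jstep
        if (jstep == 1L) {
          vw <- bedges[[b]][[wrap(j)]]; v <- vw[1L]; w <- vw[2L]
        } else {
          wv <- bedges[[b]][[wrap(j - 1L)]]; w <- wv[1L]; v <- wv[2L]
        }
        allowed[v, w] <<- TRUE; allowed[w, v] <<- TRUE
        j <- j + jstep
      }
      bw <- cs[wrap(j)]
      label[w] <<- 2L; label[bw] <<- 2L
      le_v[w] <<- v; le_w[w] <<- w; le_none[w] <<- FALSE
      le_v[bw] <<- v; le_w[bw] <<- w; le_none[bw] <<- FALSE
      bestedge[bw] <<- list(NULL)
      j <- j + jstep
      while (cs[wrap(j)] != entrychild) {
        bv <- cs[wrap(j)]
        if (label[bv] == 1L) { j <- j + jstep; next }
        v2 <- 0L
        if (bv > n) {
          for (lv in leaves(bv)) if (label[lv] != 0L) { v2 <- lv; break }
        } else if (label[bv] != 0L) {
          v2 <- bv
        }
        if (v2 != 0L) {
          label[v2] <<- 0L
          label[mate[bbase[bv]]] <<- 0L
          assign_label(v2, 2L, le_v[v2])
        }
        j <- j + jstep
      }
    }
    label[b] <<- 0L; le_none[b] <<- TRUE
    bestedge[b] <<- list(NULL)
    parent[b] <<- 0L; bbase[b] <<- 0L; bldual[b] <<- NA_real_
    childs[b] <<- list(NULL)
    bedges[b] <<- list(NULL)
    mybest[b] <<- list(NULL)
    freeb <<- c(freeb, b)
  }

  # Swap matched edges along the alternating path inside blossom b from
  # vertex v down to the blossom base, then re-root the blossom at v.
  augment_blossom <- function(b, v) {
    t <- v
    while (parent[t] != b) t <- parent[t]
    if (t > n) augment_blossom(t, v)
    cs <- childs[[b]]
    len <- length(cs)
    wrap <- function(idx) (idx %% len) + 1L
    i <- which(cs == t)[1L] - 1L
    j <- i
    jstep <- if (bitwAnd(i, 1L) > 0L) { j <- j - len; 1L } else -1L
    while (j != 0L) {
      j <- j + jstep
      t <- cs[wrap(j)]
      if (jstep == 1L) {
        wx <- bedges[[b]][[wrap(j)]]; w <- wx[1L]; x <- wx[2L]
      } else {
        xw <- bedges[[b]][[wrap(j - 1L)]]; x <- xw[1L]; w <- xw[2L]
      }
      if (t > n) augment_blossom(t, w)
      j <- j + jstep
      t <- cs[wrap(j)]
      if (t > n) augment_blossom(t, x)
      mate[w] <<- x; mate[x] <<- w
    }
    if (i > 0L) {
      childs[[b]] <<- c(cs[(i + 1L):len], cs[seq_len(i)])
      bedges[[b]] <<- c(bedges[[b]][(i + 1L):len], bedges[[b]][seq_len(i)])
    }
    bbase[b] <<- bbase[childs[[b]][1L]]
  }

  augment_matching <- function(v, w) {
    for (pair in list(c(v, w), c(w, v))) {
      s <- pair[1L]; j <- pair[2L]
      repeat {
        bs <- inblossom[s]
        if (bs > n) augment_blossom(bs, s)
        mate[s] <<- j
        if (le_none[bs]) break
        t <- le_v[bs]
        bt <- inblossom[t]
        s <- le_v[bt]; j <- le_w[bt]
        if (bt > n) augment_blossom(bt, j)
        mate[j] <<- s
      }
    }
  }

  active_blossoms <- function() which(!is.na(bldual))

  repeat {  # stage
    label[] <- 0L
    le_none[] <- TRUE
    bestedge <- vector("list", cap)
    for (b in active_blossoms()) mybest[b] <- list(NULL)
    allowed[] <- FALSE
    queue <- integer(0)
    for (v in seq_len(n))
      if (mate[v] == 0L && label[inblossom[v]] == 0L) assign_label(v, 1L, 0L)

    augmented <- FALSE
    repeat {  # substage
      while (length(queue) && !augmented) {
        v <- queue[length(queue)]
        queue <- queue[-length(queue)]
        for (w in nbr[[v]]) {
          bv <- inblossom[v]; bw <- inblossom[w]
          if (bv == bw) next
          kslack <- NA_real_
          if (!allowed[v, w]) {
            kslack <- slack(v, w)
            if (kslack <= 0) { allowed[v, w] <- TRUE; allowed[w, v] <- TRUE }
          }
          if (allowed[v, w]) {
            if (label[bw] == 0L) {
              assign_label(w, 2L, v)
            } else if (label[bw] == 1L) {
              bse <- scan_blossom(v, w)
              if (bse != 0L) {
                add_blossom(bse, v, w)
              } else {
                augment_matching(v, w)
                augmented <- TRUE
                break
              }
            } else if (label[w] == 0L) {
              label[w] <- 2L
              le_v[w] <- v; le_w[w] <- w; le_none[w] <- FALSE
            }
          } else if (label[bw] == 1L) {
            cur <- bestedge[[bv]]
            if (is.null(cur) || kslack < slack(cur[1L], cur[2L]))
              bestedge[[bv]] <- c(v, w)
          } else if (label[w] == 0L) {
            cur <- bestedge[[w]]
            if (is.null(cur) || kslack < slack(cur[1L], cur[2L]))
              bestedge[[w]] <- c(v, w)
          }
        }
      }
      if (augmented) break

      # Dual adjustment.
      deltatype <- 1L
      delta <- min(dualvar)
      deltaedge <- NULL
      deltablossom <- 0L
      for (v in seq_len(n)) {
        if (label[inblossom[v]] == 0L && !is.null(bestedge[[v]])) {
          d <- slack(bestedge[[v]][1L], bestedge[[v]][2L])
          if (d < delta) { delta <- d; deltatype <- 2L
                           deltaedge <- bestedge[[v]] }
        }
      }
      for (b in c(seq_len(n), active_blossoms())) {
        if (parent[b] == 0L && label[b] == 1L && !is.null(bestedge[[b]])) {
          d <- slack(bestedge[[b]][1L], bestedge[[b]][2L]) / 2
          if (d < delta) { delta <- d; deltatype <- 3L
                           deltaedge <- bestedge[[b]] }
        }
      }
      for (b in active_blossoms()) {
        if (parent[b] == 0L && label[b] == 2L && bldual[b] < delta) {
          delta <- bldual[b]; deltatype <- 4L; deltablossom <- b
        }
      }

      lab_of_v <- label[inblossom[seq_len(n)]]
      dualvar[lab_of_v == 1L] <- dualvar[lab_of_v == 1L] - delta
      dualvar[lab_of_v == 2L] <- dualvar[lab_of_v == 2L] + delta
      for (b in active_blossoms()) {
        if (parent[b] == 0L) {
          if (label[b] == 1L) bldual[b] <- bldual[b] + delta
          else if (label[b] == 2L) bldual[b] <- bldual[b] - delta
        }
      }

      if (deltatype == 1L) break
      if (deltatype == 2L) {
        v <- deltaedge[1L]; w <- deltaedge[2L]
        allowed[v, w] <- TRUE; allowed[w, v] <- TRUE
        queue <- c(queue, v)
      } else if (deltatype == 3L) {
        v <- deltaedge[1L]; w <- deltaedge[2L]
        allowed[v, w] <- TRUE; allowed[w, v] <- TRUE
        queue <- c(queue, v)
      } else {
        expand_blossom(deltablossom, FALSE)
      }
    }

    if (!augmented) break
    for (b in active_blossoms())
      if (!is.na(bldual[b]) && parent[b] == 0L && label[b] == 1L &&
          bldual[b] == 0) expand_blossom(b, TRUE)
  }

  mate
}
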