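# A deliberately slow pure-R replica of one simulator tick, mirroring the
# compiled implementation draw-for-draw (same RNG consumption order), but
# computing every neighborhood count by direct scan instead of the
# incrementally maintained vision fields. Agreement of full world states
# after several ticks verifies the field bookkeeping and the rejection-
# sampling move rule against first principles.

ref_step <- function(world, legitimacy, propaganda) {
  p <- world$params
  side <- p$grid_side; ncell <- side^2; v <- p$vision
  occ <- world$occupancy; state <- world$state; jail <- world$jail_remaining
  cpos <- world$citizen_pos; kpos <- world$cop_pos
  ra <- world$risk_aversion; ph <- world$perceived_hardship
  n_cit <- p$n_citizens; n_cops <- p$n_cops

  unif0 <- function(n) min(floor(runif(1) * n), n - 1)  # 0-based, mirrors C++
  wrap <- function(a) ((a %% side) + side) %% side
  vision_cells <- function(c) {  # row-major order as in the compiled scan
    span <- min(2 * v + 1, side)
    x <- (c - 1) %/% side; y <- (c - 1) %% side
    xs <- wrap(x - v + 0:(span - 1)); ys <- wrap(y - v + 0:(span - 1))
    as.vector(t(outer(xs * side, ys, "+"))) + 1L
  }
  pick_empty <- function(pos) {
    span <- min(2 * v + 1, side)
    x <- (pos - 1) %/% side; y <- (pos - 1) %% side
    for (i in seq_len(3 * span * span)) {
      xx <- wrap(x - v + unif0(span)); yy <- wrap(y - v + unif0(span))
      cc <- xx * side + yy + 1
      if (occ[cc] == 0) return(cc)
    }
    empt <- vision_cells(pos)
    empt <- empt[occ[empt] == 0]
    if (length(empt) == 0) return(0L)
    empt[unif0(length(empt)) + 1L]
  }
  move <- function(gid) {
    is_cop <- gid > n_cit
    pos <- if (is_cop) kpos[gid - n_cit] else cpos[gid]
    if (pos == 0 || v <= 0) return(invisible())
    dest <- pick_empty(pos)
    if (dest == 0) return(invisible())
    occ[pos] <<- 0L; occ[dest] <<- gid
    if (is_cop) kpos[gid - n_cit] <<- dest else cpos[gid] <<- dest
  }

  jailed_count <- sum(state == 2L)
  order_ids <- c(which(state != 2L), n_cit + seq_len(n_cops))
  if (length(order_ids) > 1) {
    for (i in (length(order_ids) - 1):1) {   # Fisher-Yates, same draw order
      j <- unif0(i + 1)
      tmp <- order_ids[i + 1]; order_ids[i + 1] <- order_ids[j + 1]
      order_ids[j + 1] <- tmp
    }
  }
  for (gid in order_ids) {
    if (gid <= n_cit) {
      if (state[gid] == 2L) next
      move(gid)
      cells <- vision_cells(cpos[gid])
      ids <- occ[cells]; ids <- ids[ids != 0]
      ncops_v <- sum(ids > n_cit)
      cit <- ids[ids <= n_cit & ids != gid]
      nact_v <- sum(state[cit] == 1L)
      r <- ncops_v %/% (nact_v + 1L)
      parr <- 1 - exp(-p$arrest_k * r)
      g <- ph[gid] * (1 - legitimacy)
      state[gid] <- if ((g - ra[gid] * parr) > propaganda) 1L else 0L
    } else {
      move(gid)
      if (jailed_count < p$jail_capacity) {
        cells <- vision_cells(kpos[gid - n_cit])
        ids <- occ[cells]
        act <- ids[ids >= 1 & ids <= n_cit]
        act <- act[state[act] == 1L]
        if (length(act) > 0) {
          cid <- act[unif0(length(act)) + 1L]
          state[cid] <- 2L
          jail[cid] <- 1L + unif0(p$max_jail_term)
          occ[cpos[cid]] <- 0L
          cpos[cid] <- 0L
          jailed_count <- jailed_count + 1L
        }
      }
    }
  }
  for (i in seq_len(n_cit)) {
    if (state[i] != 2L) next
    jail[i] <- jail[i] - 1L
    if (jail[i] <= 0L) {
      empt <- which(occ == 0L)
      if (length(empt) == 0) { jail[i] <- 1L; next }
      dest <- empt[unif0(length(empt)) + 1L]
      state[i] <- 0L; jail[i] <- 0L; cpos[i] <- dest; occ[dest] <- i
    }
  }
  out <- list(risk_aversion = ra, perceived_hardship = ph,
              state = as.integer(state), jail_remaining = as.integer(jail),
              citizen_pos = as.integer(cpos), cop_pos = as.integer(kpos),
              occupancy = as.integer(occ), t = world$t + 1L, params = p)
  class(out) <- "rebellion_world"
  out
}
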