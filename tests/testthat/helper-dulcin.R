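# Shared fixtures: experimental rotamer parameters and conformer predictions
# (the published table values embedded in the package).

rot1_constants <- function() rotational_constants(3052.1532, 304.82621, 292.43629)
rot1_distortion <- function() quartic_distortion(DJ = 0.00589, DJK = -0.128)
rot2_constants <- function() rotational_constants(2413.98, 336.70893, 319.08422)
rot2_distortion <- function() quartic_distortion(DJ = 0.0116, DJK = -0.135)

rot1_truth <- function(mu_c = 0) {
  list(constants = rot1_constants(), distortion = rot1_distortion(),
       dipoles = dipole_moment(5.1, 0, mu_c))
}

# symmetric-top closed form, the independent oracle for the diagonalization
symtop_energy <- function(A, B, J, K, DJ = 0, DJK = 0, DK = 0) {
  JJ <- J * (J + 1)
  B * JJ + (A - B) * K^2 - DJ * JJ^2 - DJK * JJ * K^2 - DK * K^4
}

# Boltzmann factors computed independently of the package (plain arithmetic)
boltz_oracle <- function(E, T) {
  w <- exp(-E / (0.6950348 * T))
  w / sum(w)
}

# exact minimax barrier by threshold connectivity: the barrier is the
# smallest level E* (over the sorted grid energies) at which start and end
# are connected in the subgraph {E <= E*}; BFS on the level set. Independent
# of the widest-path implementation in the package.
barrier_threshold_oracle <- function(E, start, end, periodic = TRUE) {
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  nr <- nrow(E); nc <- ncol(E)
  id <- function(r, c) (c - 1L) * nr + r
  if (length(start) == 1) start <- c(1L, start)
  if (length(end) == 1) end <- c(1L, end)
  s <- id(start[1], start[2]); t <- id(end[1], end[2])
  connected_at <- function(lev) {
    ok <- is.finite(E) & E <= lev
    if (!ok[s] || !ok[t]) return(FALSE)
    seen <- rep(FALSE, nr * nc)
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u == t) return(TRUE)
      r <- ((u - 1L) %% nr) + 1L
      c <- ((u - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (periodic) {
          rr <- ((rr - 1L) %% nr) + 1L
          cc <- ((cc - 1L) %% nc) + 1L
        } else if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- id(rr, cc)
        if (!seen[j] && ok[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    FALSE
  }
  for (lev in sort(unique(as.numeric(E[is.finite(E)]))))
    if (connected_at(lev)) return(lev - E[s])
  stop("disconnected")
}

# exhaustive simple-path minimax by depth-first search (tiny grids only)
barrier_dfs_oracle <- function(E, start, end, periodic = FALSE) {
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  nr <- nrow(E); nc <- ncol(E)
  id <- function(r, c) (c - 1L) * nr + r
  if (length(start) == 1) start <- c(1L, start)
  if (length(end) == 1) end <- c(1L, end)
  s <- id(start[1], start[2]); t <- id(end[1], end[2])
  best <- Inf
  visit <- function(u, pathmax, seen) {
    if (pathmax >= best) return()
    if (u == t) { best <<- pathmax; return() }
    r <- ((u - 1L) %% nr) + 1L
    c <- ((u - 1L) %/% nr) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (periodic) {
        rr <- ((rr - 1L) %% nr) + 1L
        cc <- ((cc - 1L) %% nc) + 1L
      } else if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      j <- id(rr, cc)
      if (!seen[j] && is.finite(E[j]))
        visit(j, max(pathmax, E[j]), `[<-`(seen, j, TRUE))
    }
  }
  visit(s, E[s], `[<-`(rep(FALSE, nr * nc), s, TRUE))
  best - E[s]
}
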