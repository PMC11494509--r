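# Independent oracles and tiny fixture builders shared by the tests.

# CODATA-based Coulomb factor, written out independently of the package
oracle_f_coulomb <- function() {
  6.02214076e23 * (1.602176634e-19)^2 /
    (4 * pi * 8.8541878128e-12) * 1e10 / 1e3
}

# brute-force per-residue potential: plain double loop over atoms
oracle_decompose <- function(structure, probe,
                             include = c("protein", "water", "ion",
                                         "substrate")) {
  a <- structure$atoms[structure$atoms$group_kind %in% include, ,
                       drop = FALSE]
  fc <- oracle_f_coulomb()
  keys <- paste(a$chain_id, a$residue_seq, sep = ":")
  out <- numeric(0)
  for (i in seq_len(nrow(a))) {
    r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - probe)^2))
    v <- fc * a$charge[i] / r
    k <- keys[i]
    out[k] <- if (k %in% names(out)) out[k] + v else v
  }
  out
}

# hand-built charged structure from explicit rows
make_structure <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(atom_id = i, atom_name = r$atom, residue_name = r$res,
               residue_seq = r$seq, chain_id = r$chain %||% "A",
               x = r$pos[1], y = r$pos[2], z = r$pos[3],
               charge = r$q %||% 0, stringsAsFactors = FALSE)
  }))
  charged_structure(atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom <- function(atom, res, seq, pos, q = 0, chain = "A")
  list(atom = atom, res = res, seq = seq, pos = pos, q = q, chain = chain)

# random toy structure spec used by several property tests
random_toy_spec <- function(n_res, rng_seed) {
  set.seed(rng_seed)
  toy_protein_spec(data.frame(
    name = sample(c("ASP", "LYS", "SER", "GLY"), n_res, replace = TRUE),
    net_charge = sample(c(-1, 0, 1), n_res, replace = TRUE),
    ca_distance = runif(n_res, 6, 22),
    n_atoms = sample(2:5, n_res, replace = TRUE)))
}

# exhaustive minimax path cost between two nodes on a small grid
# (simple-path enumeration by depth-first search; oracle for the
# union-find saddle computation)
oracle_minimax <- function(G, dims, from, to) {
  nbs <- function(i) {
    nx <- dims[1]; ny <- dims[2]
    ix <- (i - 1L) %% nx + 1L
    iy <- (i - 1L) %/% nx + 1L
    dx <- rep(-1:1, 3); dy <- rep(-1:1, each = 3)
    keep <- !(dx == 0 & dy == 0)
    jx <- ix + dx[keep]; jy <- iy + dy[keep]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    jx[ok] + (jy[ok] - 1L) * nx
  }
  best <- Inf
  visit <- function(i, seen, peak) {
    peak <- max(peak, G[i])
    if (peak >= best) return(invisible(NULL))
    if (i == to) { best <<- peak; return(invisible(NULL)) }
    for (j in nbs(i)) if (!seen[j]) {
      s2 <- seen; s2[j] <- TRUE
      visit(j, s2, peak)
    }
  }
  seen <- logical(length(G)); seen[from] <- TRUE
  visit(from, seen, -Inf)
  best
}
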