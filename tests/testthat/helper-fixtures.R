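## Shared fixtures and independent oracles. The oracles deliberately use a
## different computational path than the package (random-point quadrature
## instead of the Fibonacci lattice, explicit window loops, grid search
## instead of SVD) so agreement is evidence, not tautology.

## ---- tiny PDB fixture ----------------------------------------------

pdb_line <- function(record = "ATOM", serial, name, resname, chain, resseq,
                     icode = " ", x, y, z, occ = 1, bf = 0, element,
                     altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resseq, icode,
          x, y, z, occ, bf, element)
}

## One chain with residues 50..57 plus an inserted 53A (9 residues), CA only,
## mimicking heavy-chain loop numbering, plus a water and a hetero ion.
write_icode_fixture <- function(path) {
  res <- data.frame(
    resseq = c(50, 51, 52, 53, 53, 54, 55, 56, 57),
    icode = c(" ", " ", " ", " ", "A", " ", " ", " ", " "),
    resname = c("TYR", "ILE", "ASP", "PRO", "LYS", "HIS", "GLY", "GLY", "THR"),
    stringsAsFactors = FALSE)
  lines <- character(0)
  for (i in seq_len(nrow(res))) {
    lines <- c(lines, pdb_line(serial = i, name = "CA",
                               resname = res$resname[i], chain = "H",
                               resseq = res$resseq[i], icode = res$icode[i],
                               x = 3.8 * i, y = 0, z = 0, element = "C"))
  }
  lines <- c(lines,
             pdb_line("HETATM", 90, "O", "HOH", "H", 200, " ", 50, 50, 50,
                      element = "O"),
             pdb_line("HETATM", 91, "ZN", "ZN", "H", 201, " ", 60, 60, 60,
                      element = "ZN"),
             "END")
  writeLines(lines, path)
  path
}

## Minimal atom-table structure for geometric SASA tests.
atoms_structure <- function(x, y, z, radius, element = "C", name = "CA",
                            resseq = seq_along(x), chain = "A",
                            resname = "ALA") {
  n <- length(x)
  a <- data.frame(model = 1L, serial = seq_len(n),
                  name = rep_len(name, n), altloc = "",
                  resname = rep_len(resname, n),
                  chain = rep_len(chain, n),
                  resseq = rep_len(as.integer(resseq), n), icode = "",
                  x = x, y = y, z = z, occupancy = 1, bfactor = 0,
                  element = rep_len(element, n), hetero = FALSE,
                  radius = rep_len(radius, n), stringsAsFactors = FALSE)
  pepforge:::new_structure(a)
}

## ---- SASA oracles ----------------------------------------------------

## Brute-force quadrature with seeded *random* surface points.
sasa_point_oracle <- function(coords, radii, probe, n_points = 1e5,
                              seed = 99) {
  set.seed(seed)
  n <- nrow(coords)
  R <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- matrix(rnorm(n_points * 3), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * R[i]
    p <- sweep(p, 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      free <- free & d2 >= R[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * R[i]^2
  }
  areas
}

## Closed-form accessible area of two intersecting expanded spheres.
two_sphere_analytic <- function(d, r1, r2, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  cap <- function(Ra, Rb) {
    if (d >= Ra + Rb) return(0)
    if (d + Ra <= Rb) return(4 * pi * Ra^2)  # fully buried
    cost <- (d^2 + Ra^2 - Rb^2) / (2 * d * Ra)
    2 * pi * Ra^2 * (1 - cost)
  }
  c(4 * pi * R1^2 - cap(R1, R2), 4 * pi * R2^2 - cap(R2, R1))
}

## ---- hydrogen-bond oracle -------------------------------------------

## Exhaustive donor-acceptor pair scan (distance criterion only).
hbond_pair_oracle <- function(s, donors_from, acceptors_from, d_max = 3.5) {
  a <- s$atoms[s$atoms$model == min(s$atoms$model), ]
  don_names <- c("N", "NE", "NH1", "NH2", "NZ", "ND2", "NE2", "ND1",
                 "NE1", "OG", "OG1", "OH")
  acc_names <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                 "OH", "ND1", "NE2")
  don <- a[a$chain %in% donors_from & a$name %in% don_names &
             !(a$name == "N" & a$resname == "PRO"), ]
  acc <- a[a$chain %in% acceptors_from & a$name %in% acc_names, ]
  count <- 0
  for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
    same <- don$chain[i] == acc$chain[j] &&
      don$resseq[i] == acc$resseq[j] && don$icode[i] == acc$icode[j]
    if (same) next
    d <- sqrt((don$x[i] - acc$x[j])^2 + (don$y[i] - acc$y[j])^2 +
                (don$z[i] - acc$z[j])^2)
    if (d > 0.5 && d <= d_max) count <- count + 1
  }
  count
}

## ---- Conjoint-Triad oracle ------------------------------------------

## Window-enumeration with an independently written class lookup.
triad_oracle <- function(seq) {
  groups <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                 c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                 c("R", "K"), c("D", "E"), "C")
  cls <- integer(0)
  for (g in seq_along(groups)) cls[groups[[g]]] <- g
  letters <- strsplit(seq, "")[[1]]
  v <- numeric(343)
  for (i in seq_len(length(letters) - 2)) {
    c1 <- cls[[letters[i]]]; c2 <- cls[[letters[i + 1]]]
    c3 <- cls[[letters[i + 2]]]
    k <- (c1 - 1) * 49 + (c2 - 1) * 7 + c3
    v[k] <- v[k] + 1
  }
  v
}

## ---- Kabsch oracle ---------------------------------------------------

## Coarse-to-fine grid search over Euler angles; translation aligns
## centroids for each trial rotation.
rmsd_grid_oracle <- function(ref, mobile) {
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  score <- function(R) {
    m <- mobile %*% t(R)
    m <- sweep(m, 2, colMeans(ref) - colMeans(m), "+")
    sqrt(mean(rowSums((m - ref)^2)))
  }
  ## coarse full-space grid, then Nelder-Mead polish from the best starts
  gr <- expand.grid(a = seq(-pi, pi, length.out = 13),
                    b = seq(0, pi, length.out = 7),
                    c = seq(-pi, pi, length.out = 13))
  vals <- vapply(seq_len(nrow(gr)), function(k)
    score(rot(gr$a[k], gr$b[k], gr$c[k])), 1.0)
  starts <- utils::head(order(vals), 4)
  best_val <- Inf
  for (k in starts) {
    fit <- stats::optim(unlist(gr[k, ]),
                        function(p) score(rot(p[1], p[2], p[3])),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best_val <- min(best_val, fit$value)
  }
  best_val
}

## ---- clustering helper ----------------------------------------------

mean_silhouette <- function(points, labels) {
  d <- as.matrix(dist(points))
  vals <- vapply(seq_len(nrow(points)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(s) mean(d[i, labels == s]), 1.0))
    (b - a) / max(a, b)
  }, 1.0)
  mean(vals)
}
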