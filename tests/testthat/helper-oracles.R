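# Independent brute-force oracles for the interaction detectors: plain
# double/triple loops over the perceived chemistry with locally defined
# scalar geometry, no shared code with the package's grid-accelerated path.

.o_dist <- function(p, q) sqrt(sum((p - q)^2))
.o_angle <- function(a, b, c) {  # angle at b, degrees
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cs))) * 180 / pi
}
.o_xyz <- function(cx, s) {
  i <- match(s, cx$atoms$eleno)
  c(cx$atoms$x[i], cx$atoms$y[i], cx$atoms$z[i])
}

# multiset keys for exact set comparison between detector and oracle
rec_keys <- function(kind, records) {
  if (!nrow(records)) return(character(0))
  r6 <- function(x) sprintf("%.6f", x)
  k <- switch(kind,
    hbond = paste(records$lig_atom, records$prot_atom, records$subtype,
                  r6(records$distance), r6(records$donor_angle)),
    hbond_contact_docking = paste(records$lig_atom, records$prot_atom,
                                  r6(records$distance)),
    water_bridge = paste(records$lig_atom, records$residue_key,
                         records$water_key, r6(records$distance)),
    pi_pi = paste(records$lig_ring, records$prot_ring, records$subtype),
    pi_cation = paste(records$lig_ring, records$prot_ring,
                      records$lig_atom, records$prot_atom),
    hydrophobic = paste(records$residue_key, records$lig_atom,
                        records$prot_atom, r6(records$distance)),
    ionic = paste(records$lig_atom, records$prot_atom))
  sort(k)
}

oracle_docking <- function(cx, cr) {
  at <- cx$atoms
  rows <- list()
  for (hi in which(at$is_h)) {
    par <- match(at$parent[hi], at$eleno)
    if (!(at$elesy[par] %in% c("N", "O", "S"))) next
    hm <- at$moiety[hi]
    if (!(hm %in% c("ligand", "protein"))) next
    other <- setdiff(c("ligand", "protein"), hm)
    for (xi in which(!at$is_h & at$moiety == other &
                     at$elesy %in% c("N", "O", "S"))) {
      d <- .o_dist(c(at$x[hi], at$y[hi], at$z[hi]),
                   c(at$x[xi], at$y[xi], at$z[xi]))
      if (d <= cr$docking_contact_max) {
        lig <- if (hm == "ligand") at$eleno[hi] else at$eleno[xi]
        prot <- if (hm == "ligand") at$eleno[xi] else at$eleno[hi]
        rows[[length(rows) + 1L]] <- data.frame(lig_atom = lig,
                                                prot_atom = prot, distance = d)
      }
    }
  }
  if (!length(rows)) return(data.frame(lig_atom = integer(),
                                       prot_atom = integer(),
                                       distance = numeric()))
  do.call(rbind, rows)
}

# directional relaxed H-bond test used by both oracle_hbonds and bridges
.o_hb_ok <- function(cx, d_serial, h_serial, a_serial, d_max, ang_d, ang_a,
                     quantifier = "every") {
  ch <- cx$chemistry
  pd <- .o_xyz(cx, d_serial); ph <- .o_xyz(cx, h_serial); pa <- .o_xyz(cx, a_serial)
  dist <- .o_dist(pd, pa)
  if (dist > d_max) return(NULL)
  dang <- .o_angle(pd, ph, pa)
  if (dang < ang_d) return(NULL)
  xs <- ch$acceptor_neighbors$x[ch$acceptor_neighbors$a == a_serial]
  xs <- setdiff(xs, h_serial)
  if (length(xs)) {
    angs <- vapply(xs, function(x) .o_angle(ph, pa, .o_xyz(cx, x)), 1.0)
    ok <- if (quantifier == "every") all(angs >= ang_a) else any(angs >= ang_a)
    if (!ok) return(NULL)
  }
  list(dist = dist, donor_angle = dang)
}

oracle_hbonds <- function(cx, cr, quantifier = "every") {
  ch <- cx$chemistry
  rows <- list()
  for (dk in seq_len(nrow(ch$donors))) for (ak in seq_len(nrow(ch$acceptors))) {
    dono <- ch$donors[dk, ]; acc <- ch$acceptors[ak, ]
    pair_ok <- (dono$owner == "ligand" && acc$owner == "protein") ||
               (dono$owner == "protein" && acc$owner == "ligand")
    if (!pair_ok || dono$d == acc$a) next
    hit <- .o_hb_ok(cx, dono$d, dono$h, acc$a, cr$hbond_da_max,
                    cr$hbond_donor_angle_min, cr$hbond_acceptor_angle_min,
                    quantifier)
    if (is.null(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      lig_atom = if (dono$owner == "ligand") dono$d else acc$a,
      prot_atom = if (dono$owner == "ligand") acc$a else dono$d,
      subtype = paste0(dono$owner, "_donor"),
      distance = hit$dist, donor_angle = hit$donor_angle)
  }
  if (!length(rows)) return(data.frame(lig_atom = integer(),
                                       prot_atom = integer(),
                                       subtype = character(),
                                       distance = numeric(),
                                       donor_angle = numeric()))
  do.call(rbind, rows)
}

oracle_water_bridges <- function(cx, cr, quantifier = "every") {
  ch <- cx$chemistry
  at <- cx$atoms
  legs <- function(side) {
    out <- list()
    for (dk in seq_len(nrow(ch$donors))) for (ak in seq_len(nrow(ch$acceptors))) {
      dono <- ch$donors[dk, ]; acc <- ch$acceptors[ak, ]
      if (dono$d == acc$a) next
      wat_first <- dono$owner == "water" && acc$owner == side
      wat_second <- dono$owner == side && acc$owner == "water"
      if (!wat_first && !wat_second) next
      hit <- .o_hb_ok(cx, dono$d, dono$h, acc$a, cr$wb_da_max,
                      cr$wb_donor_angle_min, cr$wb_acceptor_angle_min,
                      quantifier)
      if (is.null(hit)) next
      partner <- if (wat_first) acc$a else dono$d
      water <- if (wat_first) dono$d else acc$a
      out[[length(out) + 1L]] <- data.frame(
        partner = partner, water_key = at$residue_key[match(water, at$eleno)],
        dist = hit$dist)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  ll <- legs("ligand"); pp <- legs("protein")
  res <- list()
  if (!is.null(ll) && !is.null(pp)) {
    for (i in seq_len(nrow(ll))) for (j in seq_len(nrow(pp))) {
      if (ll$water_key[i] != pp$water_key[j]) next
      res[[length(res) + 1L]] <- data.frame(
        lig_atom = ll$partner[i],
        residue_key = at$residue_key[match(pp$partner[j], at$eleno)],
        water_key = ll$water_key[i], distance = max(ll$dist[i], pp$dist[j]))
    }
  }
  if (!length(res)) return(data.frame(lig_atom = integer(),
                                      residue_key = character(),
                                      water_key = character(),
                                      distance = numeric()))
  out <- do.call(rbind, res)
  key <- paste(out$lig_atom, out$residue_key, out$water_key)
  out <- out[order(key, out$distance), , drop = FALSE]
  out[!duplicated(paste(out$lig_atom, out$residue_key, out$water_key)), ,
      drop = FALSE]
}

.o_ring_geo <- function(cx, members) {
  xyz <- t(vapply(members, function(s) .o_xyz(cx, s), numeric(3)))
  cen <- colMeans(xyz)
  m <- sweep(xyz, 2, cen)
  n <- svd(m)$v[, 3]
  list(centroid = cen, normal = n / sqrt(sum(n^2)))
}

oracle_pi_pi <- function(cx, cr) {
  ch <- cx$chemistry
  rows <- list()
  for (rl in ch$rings) for (rp in ch$rings) {
    if (rl$owner != "ligand" || rp$owner != "protein") next
    gl <- .o_ring_geo(cx, rl$members); gp <- .o_ring_geo(cx, rp$members)
    d <- .o_dist(gl$centroid, gp$centroid)
    cs <- abs(sum(gl$normal * gp$normal))
    th <- acos(max(-1, min(1, cs))) * 180 / pi
    sub <- NULL
    if (th <= cr$pipi_f2f_angle_max && d <= cr$pipi_f2f_centroid_max)
      sub <- "face_to_face"
    else if (th >= min(cr$pipi_e2f_angle_range) && d <= cr$pipi_e2f_centroid_max)
      sub <- "edge_to_face"
    if (!is.null(sub))
      rows[[length(rows) + 1L]] <- data.frame(lig_ring = rl$id,
                                              prot_ring = rp$id, subtype = sub)
  }
  if (!length(rows)) return(data.frame(lig_ring = integer(),
                                       prot_ring = integer(),
                                       subtype = character()))
  do.call(rbind, rows)
}

.o_site <- function(cx, g) {
  xyz <- t(vapply(g$site_atoms, function(s) .o_xyz(cx, s), numeric(3)))
  colMeans(xyz)
}

oracle_pi_cation <- function(cx, cr) {
  ch <- cx$chemistry
  rows <- list()
  for (r in ch$rings) for (g in ch$charges) {
    if (g$sign <= 0 || r$owner == g$owner) next
    if (!all(c(r$owner, g$owner) %in% c("ligand", "protein"))) next
    d <- .o_dist(.o_ring_geo(cx, r$members)$centroid, .o_site(cx, g))
    if (d <= cr$pication_max)
      rows[[length(rows) + 1L]] <- data.frame(
        lig_ring = if (r$owner == "ligand") r$id else NA_integer_,
        prot_ring = if (r$owner == "protein") r$id else NA_integer_,
        lig_atom = if (g$owner == "ligand") g$site_atoms[1] else NA_integer_,
        prot_atom = if (g$owner == "protein") g$site_atoms[1] else NA_integer_)
  }
  if (!length(rows)) return(data.frame(lig_ring = integer(),
                                       prot_ring = integer(),
                                       lig_atom = integer(),
                                       prot_atom = integer()))
  do.call(rbind, rows)
}

oracle_hydrophobic <- function(cx, cr) {
  ch <- cx$chemistry
  hp <- ch$hydrophobic
  lig <- hp[hp$owner == "ligand", , drop = FALSE]
  prot <- hp[hp$owner == "protein", , drop = FALSE]
  best <- list()
  for (i in seq_len(nrow(lig))) for (j in seq_len(nrow(prot))) {
    d <- .o_dist(.o_xyz(cx, lig$serial[i]), .o_xyz(cx, prot$serial[j]))
    if (d > cr$hydrophobic_max) next
    rk <- prot$residue_key[j]
    if (is.null(best[[rk]]) || d < best[[rk]]$distance)
      best[[rk]] <- data.frame(residue_key = rk, lig_atom = lig$serial[i],
                               prot_atom = prot$serial[j], distance = d)
  }
  if (!length(best)) return(data.frame(residue_key = character(),
                                       lig_atom = integer(),
                                       prot_atom = integer(),
                                       distance = numeric()))
  do.call(rbind, unname(best))
}

oracle_ionic <- function(cx, cr, quantifier = "every") {
  ch <- cx$chemistry
  hb <- oracle_hbonds(cx, cr, quantifier)
  rows <- list()
  for (g1 in ch$charges) for (g2 in ch$charges) {
    if (!(g1$owner == "ligand" && g2$owner == "protein")) next
    if (g1$sign * g2$sign >= 0) next
    d <- .o_dist(.o_site(cx, g1), .o_site(cx, g2))
    if (d > cr$ionic_max) next
    bridged <- nrow(hb) > 0 &&
      any((hb$lig_atom %in% g1$site_atoms & hb$prot_atom %in% g2$site_atoms) |
          (hb$lig_atom %in% g2$site_atoms & hb$prot_atom %in% g1$site_atoms))
    if (!bridged)
      rows[[length(rows) + 1L]] <- data.frame(lig_atom = g1$site_atoms[1],
                                              prot_atom = g2$site_atoms[1])
  }
  if (!length(rows)) return(data.frame(lig_atom = integer(),
                                       prot_atom = integer()))
  do.call(rbind, rows)
}
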