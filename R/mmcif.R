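#' Read a minimal mmCIF atom_site loop
#'
#' A deliberately small mmCIF reader covering the `atom_site` loop only:
#' atom identities, residue/chain assignment, model numbers, coordinates,
#' occupancy and B-factor. Model numbers map to coordinate frames, as in
#' [read_pdb()]. Dictionary validation and non-atom categories are out of
#' scope.
#'
#' @param x path to an mmCIF file, or mmCIF text.
#' @param water_names residue names flagged as water (case-insensitive).
#' @return A [wb_structure()].
#' @export
read_mmcif <- function(x, water_names = WATER_RESNAMES) {
  lines <- pdb_text_lines(x)
  lines <- lines[!grepl("^\\s*#", lines)]

  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx))
    stop("not a parseable mmCIF: no atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))

  # required columns and their accepted (label_*/auth_*) spellings
  need <- list(
    name    = c("label_atom_id", "auth_atom_id"),
    resname = c("label_comp_id", "auth_comp_id"),
    chain   = c("auth_asym_id", "label_asym_id"),
    resnum  = c("auth_seq_id", "label_seq_id"),
    x = "Cartn_x", y = "Cartn_y", z = "Cartn_z"
  )
  col_of <- lapply(need, function(alts) {
    hit <- match(alts, tags)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  })
  missing <- names(col_of)[is.na(unlist(col_of))]
  if (length(missing))
    stop(sprintf("mmCIF atom_site loop is missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  opt <- function(alts) { h <- match(alts, tags); h <- h[!is.na(h)]
                          if (length(h)) h[1] else NA_integer_ }
  c_serial <- opt("id"); c_elem <- opt("type_symbol")
  c_alt <- opt(c("label_alt_id", "auth_alt_id"))
  c_occ <- opt("occupancy"); c_b <- opt("B_iso_or_equiv")
  c_ins <- opt("pdbx_PDB_ins_code"); c_model <- opt("pdbx_PDB_model_num")

  body <- lines[seq(max(tag_idx) + 1, length(lines))]
  body <- trimws(body)
  body <- body[nzchar(body) & !grepl("^(loop_|data_|_)", body)]
  stop_at <- which(grepl("^(#|loop_|_\\w)", body))
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1)]
  if (!length(body)) stop("mmCIF atom_site loop has no data rows")

  fields <- strsplit(body, "\\s+")
  nf <- length(tags)
  ok <- vapply(fields, length, integer(1)) == nf
  fields <- fields[ok]
  if (!length(fields)) stop("mmCIF atom_site rows do not match the tag count")
  m <- do.call(rbind, fields)
  unq <- function(v) gsub("^['\"]|['\"]$", "", v)  # strip CIF quoting
  dotna <- function(v) ifelse(v %in% c(".", "?"), "", v)

  grab <- function(ci, default) {
    if (is.na(ci)) rep(default, nrow(m)) else dotna(unq(m[, ci]))
  }
  model <- grab(c_model, "1")
  model[!nzchar(model)] <- "1"
  model_f <- match(model, unique(model))
  n_models <- max(model_f)
  first <- model_f == 1
  n_at <- sum(first)
  if (any(tabulate(model_f) != n_at))
    stop("mmCIF models have differing atom counts")

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(grab(c_serial, NA)[first])),
    name = unq(m[first, col_of$name]),
    element = grab(c_elem, "")[first],
    resname = unq(m[first, col_of$resname]),
    resnum = suppressWarnings(as.integer(dotna(m[first, col_of$resnum]))),
    chain = dotna(unq(m[first, col_of$chain])),
    insert = grab(c_ins, "")[first],
    altloc = grab(c_alt, "")[first],
    occupancy = suppressWarnings(as.numeric(grab(c_occ, "1")[first])),
    bfactor = suppressWarnings(as.numeric(grab(c_b, "0")[first])),
    stringsAsFactors = FALSE
  )
  atoms$serial[is.na(atoms$serial)] <- seq_len(n_at)[is.na(atoms$serial)]
  atoms$resnum[is.na(atoms$resnum)] <- 1L
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0

  coords <- array(NA_real_, dim = c(n_at, 3, n_models))
  xs <- as.numeric(m[, col_of$x]); ys <- as.numeric(m[, col_of$y])
  zs <- as.numeric(m[, col_of$z])
  for (f in seq_len(n_models)) {
    sel <- model_f == f
    coords[, , f] <- cbind(xs[sel], ys[sel], zs[sel])
  }

  keep <- resolve_altlocs(atoms)
  wb_structure(atoms[keep, , drop = FALSE], coords[keep, , , drop = FALSE],
               frame_labels = unique(model), water_names = water_names)
}
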