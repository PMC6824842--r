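#' Label cellular objects (aggregates and solitary cells)
#'
#' A cellular object is one 8-connected component of the union of the live
#' and dead cell masks; solitary cells and aggregates are not distinguished
#' at this stage. Components mixing live and dead pixels form a single
#' object carrying both areas.
#'
#' @param live,dead logical matrices on the same grid.
#' @param pixel_size_um pixel pitch, um/px.
#' @return a [label_image()] of object labels.
#' @export
label_aggregates <- function(live, dead, pixel_size_um) {
  if (!identical(dim(live), dim(dead)))
    stop("label_aggregates: mask dimensions differ: ",
         paste(dim(live), collapse = "x"), " vs ",
         paste(dim(dead), collapse = "x"))
  label_image(label_components(live | dead), pixel_size_um)
}

#' Assign cellular objects to their host droplets
#'
#' Each object is assigned to the droplet with which it shares the most
#' pixels; objects sharing no pixel with any droplet are 'dry' and map to
#' `NA`. Ties are broken toward the smaller droplet id.
#'
#' @param objects,droplets [label_image()]s on the same grid.
#' @return integer vector indexed by object id; `NA` = dry.
#' @export
assign_to_droplets <- function(objects, droplets) {
  ol <- objects$labels; dl <- droplets$labels
  if (!identical(dim(ol), dim(dl)))
    stop("assign_to_droplets: grids differ: ",
         paste(dim(ol), collapse = "x"), " vs ", paste(dim(dl), collapse = "x"))
  n_obj <- max(ol)
  host <- rep(NA_integer_, n_obj)
  if (n_obj == 0) return(host)
  sel <- ol > 0 & dl > 0
  if (any(sel)) {
    # count overlap pixels per (object, droplet) pair
    o <- ol[sel]; d <- dl[sel]
    key <- paste(o, d)
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    tab <- data.frame(obj = as.integer(parts[, 1]),
                      drop = as.integer(parts[, 2]),
                      n = as.integer(cnt))
    # max overlap, ties to smaller droplet id
    tab <- tab[order(tab$obj, -tab$n, tab$drop), ]
    best <- tab[!duplicated(tab$obj), ]
    host[best$obj] <- best$drop
  }
  host
}

#' Build per-droplet and per-object quantification tables
#'
#' Converts label images and masks into the two record tables used by all
#' downstream statistics. Areas are pixel counts times `pixel_size_um^2`.
#' A droplet's live/dead areas count only live/dead pixels inside the
#' droplet mask (pixels of objects protruding beyond the droplet boundary
#' are excluded), so `cell_area_um2 <= area_um2` always holds. Objects with
#' no host droplet ('dry') are retained so population totals are conserved.
#'
#' @param droplets,objects [label_image()]s on the same grid.
#' @param live,dead logical masks on the same grid.
#' @param assignment integer vector from [assign_to_droplets()].
#' @param pixel_size_um pixel pitch, um/px.
#' @param field_id field-of-view identifier ('repeat').
#' @return list with data frames `droplets` (droplet_id, field_id, area_um2,
#'   x_um, y_um, cell_area_um2, live_area_um2, dead_area_um2) and `objects`
#'   (aggregate_id, field_id, area_um2, host_droplet_id, host_droplet_area_um2,
#'   live_area_um2, dead_area_um2, survival_rate).
#' @export
build_tables <- function(droplets, objects, live, dead, assignment,
                         pixel_size_um, field_id = "1") {
  dl <- droplets$labels; ol <- objects$labels
  dims <- list(droplets = dim(dl), objects = dim(ol), live = dim(live),
               dead = dim(dead))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("build_tables: inconsistent grids: ",
         paste(names(dims), vapply(dims, paste, "", collapse = "x"),
               sep = "=", collapse = ", "))
  n_drop <- max(dl); n_obj <- max(ol)
  if (length(assignment) != n_obj)
    stop("build_tables: assignment covers ", length(assignment),
         " objects but the label image has ", n_obj)
  if (any(live & dead))
    stop("build_tables: live and dead masks overlap")
  px2 <- pixel_size_um^2

  tab0 <- function(idx, nb) if (nb == 0) numeric(0) else
    tabulate(idx, nbins = nb)
  drop_px <- tab0(dl[dl > 0], n_drop)
  # centroid per droplet
  if (n_drop > 0) {
    xs <- row(dl)[dl > 0]; ys <- col(dl)[dl > 0]; ids <- dl[dl > 0]
    cx <- (vapply(split(xs, ids), mean, 1) - 0.5) * pixel_size_um
    cy <- (vapply(split(ys, ids), mean, 1) - 0.5) * pixel_size_um
  } else cx <- cy <- numeric(0)
  in_drop_live <- tab0(dl[dl > 0 & live], n_drop)
  in_drop_dead <- tab0(dl[dl > 0 & dead], n_drop)

  drops <- data.frame(droplet_id = seq_len(n_drop),
                      field_id = rep(field_id, n_drop),
                      area_um2 = drop_px * px2,
                      x_um = unname(cx), y_um = unname(cy),
                      cell_area_um2 = (in_drop_live + in_drop_dead) * px2,
                      live_area_um2 = in_drop_live * px2,
                      dead_area_um2 = in_drop_dead * px2)

  obj_px <- tab0(ol[ol > 0], n_obj)
  obj_live <- tab0(ol[ol > 0 & live], n_obj)
  obj_dead <- tab0(ol[ol > 0 & dead], n_obj)
  surv <- ifelse(obj_live + obj_dead > 0, obj_live / (obj_live + obj_dead),
                 NA_real_)
  host_area <- ifelse(is.na(assignment), NA_real_,
                      drops$area_um2[assignment])
  objs <- data.frame(aggregate_id = seq_len(n_obj),
                     field_id = rep(field_id, n_obj),
                     area_um2 = obj_px * px2,
                     host_droplet_id = assignment,
                     host_droplet_area_um2 = host_area,
                     live_area_um2 = obj_live * px2,
                     dead_area_um2 = obj_dead * px2,
                     survival_rate = surv)
  list(droplets = drops, objects = objs)
}
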