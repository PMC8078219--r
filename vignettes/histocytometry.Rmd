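---
title: "Histo-cytometry with histocyto: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histo-cytometry with histocyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis model

`histocyto` operates downstream of image segmentation. Its unit of analysis
is the Cell Of Interest (COI): a nucleus detected in a 3D confocal stack,
reduced to a single 2D record. The reduction follows the standard
histo-cytometry recipe:

1. **Central slice.** For each labeled nucleus the optical section with the
   largest cross-sectional pixel area is chosen; all 2D measurements are
   taken there. Ties go to the lower slice index, so the choice is
   deterministic and the z-reversal symmetry holds up to that tie-break.
2. **Membrane ring.** Surface markers live on the plasma membrane, not in
   the nucleus, so channel intensity is measured in an annulus around the
   nucleus: all pixels whose Euclidean distance `d` to the nearest nucleus
   pixel satisfies `inner_margin < d <= inner_margin + thickness`. The
   defaults (`inner_margin = 1` px, `thickness = 3` px) put a 3-pixel band
   over the membrane of a typical lymphocyte at confocal resolution; both
   are `ring_spec()` parameters because the right values depend on
   magnification and cell type. In dense tissue neighboring annuli collide;
   each contested pixel is assigned to the cell whose nucleus is nearest
   (ties to the lower id), so no pixel is counted twice. The ring statistic
   is the **mean** pixel value; median or integrated alternatives would be
   easy to add but the mean is what downstream gates assume.
3. **Contour and morphology.** The outer boundary of the unrestricted
   annulus is traced into a closed polygon — the shape stored in `roi.zip`
   and drawn by the overlay renderer. Morphology comes from that polygon:
   area by the shoelace formula (px²), circularity `4·pi·area/perimeter²`
   clamped to at most 1, solidity `area / convex-hull area`. Because the
   contour follows pixel boundaries, circularity of a rasterized disc lands
   around 0.85–0.95 rather than 1; the values are comparable between cells,
   which is what gating needs.

Intensities are kept on the 0–255 scale throughout. 16-bit input is mapped
linearly from the full [0, 65535] range (not min–max of the data), so
intensities remain comparable across images of one staining panel.

## Image handling

Stacks load from multi-page grayscale TIFF, by default in slice-major page
order (all channels of slice 1, then slice 2, ...); a `channel_order`
argument covers the transposed layout. An image whose larger side exceeds
1024 px is shrunk proportionally so the larger side becomes 1024. Resampling
is exact area-averaging (separable overlap-weight matrices): each output
pixel is the mean of the input area it covers, which preserves
mean-intensity statistics; target dimensions round half-up. Loading an
already-compliant image leaves pixels untouched. Contours and table
coordinates measured on the original image follow via
`rescale_geometry()` (lengths scale by the factor, areas by its square; the
original values are kept for export).

Display composition assigns each channel a color from a fixed
red/green/blue/magenta/yellow/cyan cycle keyed by channel index (overridable
per call), sums the colored channels, multiplies by the brightness gain and
clips to [0, 255]. The per-pixel result is monotone in gain until clipping —
brightness can be turned up without reordering intensities.

## Spatial context

**Regions.** Tissue regions of high cell density (e.g. the proliferation
area at the periphery of a T-cell zone) are found by DBSCAN on the 2D
centroids of the cells, ignoring z: axial spacing is anisotropic and section
stacks are thin, so 2D density is the meaningful quantity. `eps` (px) and
`min_pts` have no universally right values; the defaults (50 px, 5) are
documented as arbitrary starting points, and the synthetic preset sets
`eps` to twice the planted cell spacing. Border points reachable from two
clusters go to the cluster discovered first with ids processed ascending,
which makes labels independent of input order. The resulting 0/1 membership
is written to the `ROI_DBSCAN` column.

**Contacts.** A cell "interacts" with a partner population (e.g.
phagocytes) when its contour polygon, dilated by `contact_dist` px
(Euclidean), overlaps at least one partner-positive pixel on the cell's own
slice. The partner mask is a thresholded channel; the threshold is a
parameter because staining brightness varies. Flags are monotone in
`contact_dist` by construction. Overlap-after-dilation was chosen over
shared-boundary-length criteria because it is robust to 1–2 px segmentation
jitter and has an obvious physical reading ("within `contact_dist` pixels of
a phagocyte").

## Gating conventions

All selection geometry uses one boundary rule: closed intervals everywhere,
and a cell exactly at a threshold belongs to the at-or-above (upper/right /
second) class. The rule is arbitrary but uniform — quadrant populations
partition the filtered set exactly, and rectangle membership equals a
degenerate two-sided filter. Lasso gates use ray casting with points on the
polygon edge counted inside, matching what users expect when they draw
around points. Multiple-selection mode is plain set union with ids returned
ascending. Gate files are JSON with a `schema_version` field and geometry in
data units, so gates transfer across images; files from a newer schema fail
loudly instead of misparsing. Annotation edits apply in order with a
last-wins rule for conflicts (warned), and the audit log contains enough to
revert any edit.

## The ImageJ .roi codec and the zip container

Contours interchange in the binary ImageJ ROI format: `Iout` magic, 64-byte
big-endian header (type, bounding box, vertex count, stack position),
vertices as signed 16-bit offsets from the bounding-box corner. The codec
writes version 227 polygon ROIs with the slice in the position field and
accepts polygon, freehand and traced outlines; other types (oval, line,
point) are refused by name, and extents beyond the 16-bit range are an
explicit overflow error. Archive entries are named by zero-padded cell id
(`0042.roi`); Fiji's position-style `nnnn-yyyy-xxxx` names are accepted on
read (slice from the first field when the position field is unset, ids then
assigned by entry order with a warning). The zip container is written by a
small internal writer — stored (uncompressed) entries, CRC-32, fixed
timestamps — so identical inputs give byte-identical archives; reading goes
through base R's `unzip()` and accepts deflated archives from other tools.

## The synthetic scene generator

`generate_bundle()` exists so every stage has a falsifiable ground truth.
The default preset mirrors the canonical study design: a 1024×768 px,
12-slice, 6-channel image of 176 proliferative cells (channels for the
proliferation marker, B cells, T cells, phagocytes, an activation marker and
nuclei), reported on 10 parameters, with T/B/double-negative populations
(70/70/36), half the cells packed into one dense region, and 30% of cells
planted in contact with phagocyte blobs.

Construction guarantees recoverability rather than realism:

* Nuclei are spheres (radius 4–5 px, axial spacing 2 px/slice) centered
  exactly on a slice, so the largest cross-section — and hence the central
  slice — is unique.
* Membranes are painted as annuli covering distance (0, 6] px from the
  nucleus, a superset of the default measurement ring, with one integer
  intensity per cell and channel drawn from the population's mean ± SD
  (defaults 180 vs 30 ± 10 for the discriminating channels — a separation
  of many population SDs, comfortably beyond the ≥ 4 SD regime where
  midpoint quadrant gating is essentially error-free).
* Cells keep enough mutual clearance (≥ ~23 px center-to-center) that no
  ring overlaps foreign paint: with zero noise, measured ring means equal
  painted values *exactly*, and the noise-SD-5 default recovers population
  means to a fraction of an intensity unit at n ≈ 50.
* Dense-region members sit on a jittered square grid (spacing 26 px, jitter
  ±1 px) inside a disc, so with `eps = 52` every member has well over
  `min_pts` neighbors; sparse cells keep at least 56 px from each other and
  from the cluster, beyond `eps`, so they are pure noise points. Membership
  recovery is by construction 100%.
* Phagocyte blobs (radius 2 px) are planted overlapping their target's
  contour and kept clear of every other cell, so `contact_dist = 2`
  recovers exactly the planted flags.
* Pixel noise is Gaussian (SD 5 by default), rounded and clipped to
  [0, 255].

One RNG stream, seeded from `scene_spec(seed =)`, is consumed in a fixed
order (placement → radii/slices → intensities → contacts → noise), so a
seed pins the bundle byte-for-byte.

What the generator does **not** emulate: point-spread blur, channel
bleed-through, autofluorescence, intensity gradients with depth, irregular
nucleus shapes, touching cells and segmentation errors. Passing the
recovery checks therefore validates the *computational* pipeline — formats,
geometry, statistics, flags — not robustness to microscopy artifacts; on
real data, ring size, DBSCAN parameters and the partner threshold all need
tuning, and the annotation tools exist precisely because segmentation and
identity calls fail sometimes.

## Degenerate inputs and numerical corners

* A ring left empty after territory exclusion warns and yields `NA`
  intensities, which propagate to the CSV.
* Contours of 1–2 pixel masks fall back to the pixel square so every cell
  has a valid polygon.
* Empty tables, empty gates and empty archives are all legal; statistics
  keep zero-count rows instead of dropping them.
* Results CSVs write doubles with 17 significant digits, so a write→read
  cycle reproduces the table exactly.
* Validation reports offending rows and columns (e.g. intensities outside
  [0, 255]) rather than failing wholesale.

## Problem sizes

The test suite runs entirely on generated data: unit scenes of 10–52 cells
on 360–700 px images, property tests with up to 1000-row tables and
200-point DBSCAN instances, 1000-polygon codec round trips, and one full
176-cell default preset for the end-to-end check. These sizes keep the
whole suite under a couple of minutes on one CPU while exercising every
code path at the scale the canonical use case actually has.

## Known limitations

* Only polygon-family ROI types are supported; composite ROIs, sub-pixel
  coordinates (rounded on read) and TIFF-embedded overlays are not.
* Pyramidal/tiled image formats are out of scope; stacks are loaded whole.
* DBSCAN is exact but O(n²) in memory and time — fine for thousands of
  cells per section, not for millions.
* Neighborhood statistics beyond region membership (cluster composition,
  nearest-neighbor spectra) are deliberately not implemented here.
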