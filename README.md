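# endorecon

Feature-based 3D surface reconstruction and motion tracking for rectified
parallel binocular endoscope video, with a fully synthetic, ground-truthed
stereo scene generator for end-to-end evaluation.

In minimally invasive surgery a stereo endoscope films a deforming
soft-tissue surface (for example a beating heart). From each rectified
left/right frame pair the package:

1. detects corner features (FAST-9 with non-maximum suppression),
2. matches them *without descriptors* by classifying the 16×16 patch around
   each corner with a small convolutional network (2 convolution + 2 fully
   connected layers, softmax over the `n` feature categories), keeping per
   image at most one feature per category via a match matrix and
   intersecting the two matrices,
3. recovers 3D coordinates from horizontal disparity,
4. triangulates the sparse 3D point cloud by plane projection with a
   from-scratch incremental Delaunay triangulator, and
5. tracks the 3D position of each feature category across frames, marking
   failed frames blank and optionally filling gaps with the mean of the
   adjacent observations.

## The model

For a parallel rig with focal length *f*, baseline *b* and a scene point
*P = (X, Y, Z)* in the left camera frame, the rectified projection is

    x_l = f X / Z        x_r = f (X − b) / Z        y_l = y_r = f Y / Z

so corresponding points share their vertical coordinate ("only horizontal
parallax"). With disparity *d = x_l − x_r* the inverse is

    X = b x_l / d        Y = b y / d        Z = b f / d

Matching is classification-based: a trained network assigns each feature a
category *c* and probability *p*; per image a match matrix retains, for
every category, the single feature with the highest *p* (strict-inequality
updates, so the earliest-seen feature wins exact ties), and categories
retained in **both** views become match pairs. The surface is the Delaunay
triangulation of the matched points' projections on the left imaging plane
(Bowyer–Watson cavity insertion; Lawson's LOP edge-flip pass as a repair /
verification step), lifted unchanged to 3D and textured from the left
image.

## Worked example

```r
library(endorecon)

# a compact synthetic study: 12 blob-textured markers on a deforming
# surface at ~10 mm depth, 8 stereo frames
scene <- generate_scene(scene_config(n_markers = 12, n_frames = 8, seed = 4))

# train the matcher on the first 4 frames (persistent feature categories
# are discovered by nearest-neighbour chaining, lambda = 30 %)
fit <- fit_matcher(scene$left[1:4], epochs = 25, learning_rate = 2e-3,
                   conv1 = 24, conv2 = 48, fc = 256, seed = 1)
fit$categories[1:3, ]
#>   category   u   v n_seen
#> 1        1 126  48      4
#> 2        2 189 153      3
#> 3        3 105  82      4

# match a held-out frame pair and reconstruct the textured surface
m <- frame_matches(scene$left[[6]], scene$right[[6]], fit$model)
head(m, 3)
#>   category  lu  lv  ru  rv     lprob     rprob
#> 1        1 134  39  68  39 0.4923892 0.4794481
#> 2        2 173 136 107 136 0.3018824 0.2834601
#> 3        3 113  73  47  73 0.4510502 0.3567740

rec <- reconstruct_surface(m, scene$config$cam,
                           image_size = scene$config$image_size,
                           left_image = scene$left[[6]])
rec$mesh
#> <surface_mesh> 11 vertices, 14 faces, textured
export_mesh(rec$mesh, "surface.obj")   # or format = "ply"

# score against the generator's ground truth
ev <- evaluate_pipeline(scene, list(m), 6)
c(accuracy = ev$matching$accuracy, err_pct = ev$matching$error_pct_of_depth)
#>  accuracy   err_pct
#> 1.0000000 0.2426877
```

Every match in this frame joins the correct marker in both views, and the
mean 3D error of the reconstructed vertices is ≈ 0.24 % of the surface
depth (the residual is integer-pixel detection quantization; one pixel of
disparity at the default geometry is ≈ 1.5 % of depth, and errors largely
cancel because both views latch onto the same pattern).

Longer sequences support tracking: `track_categories()` follows chosen
categories (conventionally the three nearest the feature centroid,
`select_tracking_points()`), `fill_gaps()` applies the adjacent-frame mean
to blanks, and `motion_summary()` reports per-axis ranges plus the dominant
period via autocorrelation — for the default scene, 18.75 frames at 25 fps,
i.e. 80 cycles per minute.

A thin command-line wrapper is installed at `inst/cli/endorecon` with
subcommands `synth`, `train`, `match`, `reconstruct` and `track`; see
`pipeline_config()` for the YAML configuration schema and
`inst/extdata/example-config.yaml` for a complete example (camera block:
f = 1 mm, b = 0.99 mm).

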