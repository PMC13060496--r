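# File formats

## Volumes — NIfTI-1 (`.nii`, `.nii.gz`)

Read and written through RNifti. Conventions:

- World coordinates in mm; the affine is stored as the sform (code 2).
- The anterior–posterior (AP) axis is the **third voxel axis** by package
  convention. `read_volume(path, ap_axis = ...)` (and the CLI flag
  `--ap-axis`) permute other layouts on input.
- Label volumes are integer (`int32`); intensity volumes `double`.
- RGB volumes store channels as a 4th dimension of size 3; channel order is
  preserved across a round trip.
- For non-uniformly spaced slice stacks, per-slice AP coordinates are
  supplied separately (CLI: `--coords coords.txt`, one mm value per line);
  the NIfTI affine alone cannot express uneven spacing.

## Meshes — ASCII OFF (`.off`)

```
OFF
<n_vertices> <n_faces> 0
x y z            # n_vertices lines, world mm
3 i j k          # n_faces lines, zero-based vertex indices, triangles only
```

Optional per-vertex parcel labels travel in a sidecar file
`<path>.labels` with one integer per line (length = vertex count).

## Checkpoints

`save_checkpoint()` writes a single-file RDS archive:
`format = "slabimpute-checkpoint"`, a `version` field, the full parameter
set with architecture metadata, and an optional training-config hash.
Save/load round trips reproduce forward outputs bit-exactly.

## Configurations — YAML

`write_run_config()` / `read_run_config()` serialize any plain list (e.g.
`synth_config()` + `train_config()`) losslessly; the CLI `--config` flags
accept these files.

## Metric tables — TSV

`slabimpute evaluate ...` writes tab-separated tables with a header row;
the surface/thickness tables append a grand-mean row with an `NA` parcel.
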