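#!/usr/bin/env python
"""HDF5 bridge for MEA spike recordings.

Layout: group /spikes with one 1-D float64 dataset per electrode named e<k>;
root attributes duration_s, device_id, well_id, condition, timepoint.

Subcommands:
  dump <file.h5> <out.json>   write the recording as JSON (full precision)
  load <in.json> <file.h5>    write the JSON recording as HDF5
"""
import json
import sys

import h5py


def dump(h5_path, json_path):
    with h5py.File(h5_path, "r") as f:
        if "spikes" not in f:
            sys.exit("malformed HDF5 file: missing group /spikes")
        out = {
            "duration_s": float(f.attrs["duration_s"]),
            "device_id": str(f.attrs.get("device_id", "device1")),
            "well_id": str(f.attrs.get("well_id", "well1")),
            "condition": str(f.attrs.get("condition", "0")),
            "timepoint": str(f.attrs.get("timepoint", "baseline")),
            "spikes": {},
        }
        for name, ds in f["spikes"].items():
            if not name.startswith("e"):
                sys.exit("malformed HDF5 file: unexpected dataset /spikes/%s" % name)
            out["spikes"][name] = [float(v) for v in ds[()]]
    with open(json_path, "w") as fh:
        # repr() round-trips float64 exactly
        json.dump(out, fh)


def load(json_path, h5_path):
    with open(json_path) as fh:
        rec = json.load(fh)
    with h5py.File(h5_path, "w") as f:
        f.attrs["duration_s"] = float(rec["duration_s"])
        for key in ("device_id", "well_id", "condition", "timepoint"):
            f.attrs[key] = str(rec[key])
        g = f.create_group("spikes")
        for name, times in rec["spikes"].items():
            if isinstance(times, (int, float)):
                times = [times]
            g.create_dataset(name, data=[float(v) for v in times], dtype="f8")


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in ("dump", "load"):
        sys.exit(__doc__)
    if sys.argv[1] == "dump":
        dump(sys.argv[2], sys.argv[3])
    else:
        load(sys.argv[2], sys.argv[3])
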