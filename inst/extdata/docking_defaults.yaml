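# Site-specific docking defaults used when preparing pre-training poses.
# The search box is centered on the reference ligand of the template
# complex that shares the target protein.
engine: smina
box_size_angstrom: [22.5, 22.5, 22.5]
exhaustiveness: 8
seed: 2022
poses_per_pair: 9
use_pose_rank: 1
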