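## Shared vocabulary: the four-level movement factor and the joint sets
## defining the arm and leg limb categories.

MOVEMENT_LEVELS <- c("neither", "arm", "leg", "both")
ARM_JOINTS <- c("shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
                "wrist_l", "wrist_r")
LEG_JOINTS <- c("hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r")
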