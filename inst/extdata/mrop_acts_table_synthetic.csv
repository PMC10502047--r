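# Modified ROP Activity Scale (mROP-ActS) lookup, SYNTHETIC reconstruction v1.0.
# The published per-combination values live in a supplement that is not
# redistributed here; this table is a reconstruction constrained to every
# property the scale's description states in print: values 0-22; stage 0
# (incomplete vascularization, any zone) = 0; stage 5 (any zone) = 22;
# stage-1 entries within 1-10, stage-2 within 2-12, stage-3 within 5-16;
# plus increments across stages 1-3 of {5,2,0} in Zone I, {8,6,0} in
# Zone II, {4,3,0} in Zone III; endpoint stages 0/4/5 bundled (plus = ANY);
# no Posterior Zone II, Pre-Plus, regression or reactivation entries.
zone,stage,plus,value,label
I,0,ANY,0,MILD
II,0,ANY,0,MILD
III,0,ANY,0,MILD
I,1,NONE,5,MODERATE
I,1,PLUS,10,SEVERE
II,1,NONE,2,MILD
II,1,PLUS,10,SEVERE
III,1,NONE,1,MILD
III,1,PLUS,5,MODERATE
I,2,NONE,10,SEVERE
I,2,PLUS,12,SEVERE
II,2,NONE,6,MODERATE
II,2,PLUS,12,SEVERE
III,2,NONE,2,MILD
III,2,PLUS,5,MODERATE
I,3,NONE,16,SEVERE
I,3,PLUS,16,SEVERE
II,3,NONE,11,SEVERE
II,3,PLUS,11,SEVERE
III,3,NONE,5,MODERATE
III,3,PLUS,5,MODERATE
I,4,ANY,20,SEVERE
II,4,ANY,20,SEVERE
III,4,ANY,20,SEVERE
I,5,ANY,22,SEVERE
II,5,ANY,22,SEVERE
III,5,ANY,22,SEVERE
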