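age_category,inconclusive,under_4h,over_4h,overlapping_4h
inconclusive,1,3,0,3
under_4h,1,20,3,12
over_4h,0,3,6,4
overlapping_4h,3,4,6,12
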