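# TeleROP-SS points allocation, table version 1.0 (ICROP3 vocabulary)
# category: zone | stage | regression | plus | override | adverse | threshold
category,token,points
zone,I,30
zone,PII,20
zone,II,15
stage,0,0
stage,1,3
stage,2,10
stage,3,25
regression,REGRESS,10
regression,REGRESS-VEGFI,10
regression,REGRESS-LASER,10
plus,NONE,0
plus,PRE,5
plus,PLUS,30
override,AROP,85
adverse,4A,86
adverse,4B,89
adverse,5A,90
adverse,5B,95
adverse,5C,100
threshold,TW,55
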