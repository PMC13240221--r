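subject_id,group,findings,endomysial_ct,oil_red_o,ragged_red_fibers,cox_negative_fibers,type1_fraction,type2_fraction,mhcdn_positive_fibers,diagnosis
BI5,YUA,"Sporadic atrophic fibers",slight_increase,middle,0,0,~70%-80%,~30%-40%,0,
BK1,YUA,"None",slight_increase,small,0,0,~80%-90%,~20%-30%,2,
BW3,YUA,"Sporadic atrophic fibers",slight_increase,middle,0,0,~60%,~40%-50%,5,
CQ1,YUA,"Sporadic atrophic fibers",normal,small,0,0,~70%-80%,~30%-40%,0,
EJ9,YUA,"Sporadic atrophic fibers",normal,middle,0,1,~80%,~30%,0,unspecific_myopathological
GI3,YUA,"One atrophic fiber",slight_increase,small,0,0,~60%,~30%-40%,1,
GM5,YUA,"Sporadic atrophic fibers",slight_increase,small,0,1,~70%-80%,~30%-40%,3,
IF3,YUA,"Sporadic atrophic fibers, one nuclear clump",normal,small,0,0,~70%-80%,~20%-30%,0,unspecific_myopathological
KB5,YUA,"Sporadic atrophic fibers",slight_increase,middle,0,0,~80%-90%,~20%,1,
PN8,YUA,"Two nuclear clumps",slight_increase,middle,0,0,~80%-90%,~30%,0,
RL4,YUA,"Sporadic nuclear clumps",slight_increase,small,0,0,~80%-90%,~20%-30%,3,
SF6,YUA,"Sporadic atrophic fibers",normal,small,0,0,~90%,~10%-20%,0,
DK8,YPT,"Sporadic atrophic fibers",slight_increase,small,0,0,~60%,~40%-50%,0,
GA5,YPT,"One degenerating fiber, one atrophic fiber",normal,middle,0,0,~50%,~50%,2,
GY6,YPT,"Sporadic atrophic fibers, two nuclear clumps",slight_increase,small,0,0,~80%,~30%,0,
KO7,YPT,"One degenerating fiber, multiple atrophic fibers, sporadic nuclear clumps",slight_increase,small,0,0,~70%,~40%-50%,35,
PJ8,YPT,"Sporadic atrophic fibers",slight_increase,middle,0,0,~70%-80%,~20%-30%,0,unspecific_myopathological
QC6,YPT,"None",slight_increase,middle,0,1,~70%-80%,~40%-50%,0,
QH5,YPT,"None",normal,small,0,0,~80%,~30%,0,
RM9,YPT,"Sporadic atrophic fibers",normal,small,0,0,~80%-90%,~30%-40%,0,
RP9,YPT,"None",slight_increase,small,0,0,~70%-80%,~30%-40%,2,
WL2,YPT,"Sporadic atrophic fibers",slight_increase,middle,0,0,~70%-80%,~20%-30%,13,
CC7,AUA,"Sporadic atrophic fibers",slight_increase,small,0,0,~60%,~40%,8,unspecific_myopathological
HA4,AUA,"Sporadic atrophic fibers",normal,small,0,2,~70%,~30%-40%,4,unspecific_myopathological
IK8,AUA,"One nuclear clump",normal,small,0,2,~70%-80%,~20%-30%,1,
MS7,AUA,"One degenerating fiber, multiple atrophic fibers, sporadic nuclear clumps, >3% fibers with centralized nuclei",slight_increase,middle,4,1,~70%-80%,~30%-40%,39,chronic_neurogenic_atrophy
QP4,AUA,"Sporadic atrophic fibers",normal,small,0,0,~70%-80%,~30%,4,
RR9,AUA,"Sporadic atrophic fibers, sporadic nuclear clumps",slight_increase,small,0,0,~60%,~40%-50%,3,
TN6,AUA,"Sporadic atrophic fibers, >3% fibers with centralized nuclei",slight_increase,small,1,3,~60%,~40%-50%,0,unspecific_myopathological
UI2,AUA,"Sporadic atrophic fibers, sporadic nuclear clumps",slight_increase,small,0,3,~90%,~30%-40%,0,
VP2,AUA,"Sporadic atrophic fibers, sporadic nuclear clumps",normal,middle,0,1,~90%,~20%-30%,12,
XF8,AUA,"Sporadic nuclear clumps",normal,small,0,1,~70%-80%,~40%-50%,11,
YQ2,AUA,"Sporadic atrophic fibers, sporadic nuclear clumps",slight_increase,small,0,5,~80%-90%,~20%-30%,3,
DP4,APT,"Sporadic atrophic fibers",slight_increase,small,1,3,~80%,~40%,12,unspecific_myopathological
DY6,APT,"Sporadic regenerating fibers, sporadic atrophic fibers, sporadic nuclear clumps",slight_increase,small,1,0,~70%-80%,~30%-40%,10,chronic_neurogenic_atrophy
ED5,APT,"One endomysial and one perimysial inflammatory infiltrate, groups of atrophic fibers, sporadic nuclear clumps, >3% fibers with centralized nuclei",slight_increase,coarse,3,2,~90%,~10%,18,unspecific_myositic
FP7,APT,"One regenerating fiber, sporadic atrophic fibers",slight_increase,coarse,0,0,~100%,~10%,7,type2_fiber_atrophy
HR9,APT,"Two atrophic fibers, two nuclear clumps",slight_increase,small,0,0,~90%,~15%,10,unspecific_myopathological
LP1,APT,"Sporadic atrophic fibers",slight_increase,small,1,0,~90%-100%,~10%-20%,14,unspecific_myopathological
OY5,APT,"One regenerating fiber, sporadic nuclear clumps",normal,small,0,0,~80%,~30%-40%,7,chronic_neurogenic_atrophy
VO8,APT,"Sporadic atrophic fibers, one nuclear clump",slight_increase,small,0,0,~90%,~10%,16,unspecific_myopathological
XV3,APT,"One regenerating fiber, groups of atrophic fibers, sporadic nuclear clumps",slight_increase,small,0,0,~90%,~20%,18,chronic_neurogenic_atrophy
YB2,APT,"Sporadic atrophic fibers",normal,small,0,0,~90%,~10%,0,unspecific_myopathological
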