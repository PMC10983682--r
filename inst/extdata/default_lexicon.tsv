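surface	match_kind	script	indicator_id	profiles	comment
# Indicator 1: performance status is poor or deteriorating
poor performance status	literal	segmented	1	strict,relaxed	
deteriorating performance status	literal	segmented	1	strict,relaxed	
performance status is poor	literal	segmented	1	strict,relaxed	
performance status is deteriorating	literal	segmented	1	strict,relaxed	
bedridden	literal	segmented	1	relaxed	broader synonym
bedbound	literal	segmented	1	relaxed	broader synonym
functional decline	literal	segmented	1	relaxed	broader synonym
treatment has limited effect	literal	segmented	1	relaxed	
# Indicator 2: depends on others for care
depends on others for care	literal	segmented	2	strict,relaxed	
dependent on others for care	literal	segmented	2	strict,relaxed	
depends on others	literal	segmented	2	relaxed	broader synonym
increasing care needs	literal	segmented	2	relaxed	broader synonym
total care	literal	segmented	2	relaxed	broader synonym
# Indicator 3: the carer requires more help and support
carer requires more help and support	literal	segmented	3	strict,relaxed	
carer requires more help	literal	segmented	3	strict,relaxed	
caregiver strain	literal	segmented	3	relaxed	broader synonym
caregiver burden	literal	segmented	3	relaxed	broader synonym
carer exhausted	literal	segmented	3	relaxed	broader synonym
# Indicator 4: significant weight loss or remains underweight
significant weight loss	literal	segmented	4	strict,relaxed	
weight loss	literal	segmented	4	relaxed	broader synonym
underweight	literal	segmented	4	relaxed	broader synonym
hyposthenic build	literal	segmented	4	relaxed	broader synonym
thinner	literal	segmented	4	relaxed	broader synonym
# Indicator 5: persistent symptoms despite best available treatment
persistent symptoms despite treatment	literal	segmented	5	strict,relaxed	
persistent symptoms	literal	segmented	5	strict,relaxed	
intractable pain	literal	segmented	5	strict,relaxed	
pain	literal	segmented	5	relaxed	symptom keyword
dyspnea	literal	segmented	5	relaxed	symptom keyword
edema	literal	segmented	5	relaxed	symptom keyword
delirium	literal	segmented	5	relaxed	symptom keyword
xerostomia	literal	segmented	5	relaxed	symptom keyword
ascites	literal	segmented	5	relaxed	symptom keyword
dysphagia	literal	segmented	5	relaxed	symptom keyword
anorexia	literal	segmented	5	relaxed	symptom keyword
# Indicator 6: patient or family asks for palliative care / goals of care
asks for palliative care	literal	segmented	6	strict,relaxed	
requests palliative care	literal	segmented	6	strict,relaxed	
palliative care	literal	segmented	6	relaxed	broader synonym
focus on quality of life	literal	segmented	6	relaxed	
wishes to stop treatment	literal	segmented	6	relaxed	
# Negation cues (script column = direction, indicator_id column = token window)
no	cue	pre	3		
not	cue	pre	3		
denies	cue	pre	3		
denied	cue	pre	3		
without	cue	pre	3		
absent	cue	post	2		
# Scope breakers cutting negation scope
.	breaker				
;	breaker				
but	breaker				
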