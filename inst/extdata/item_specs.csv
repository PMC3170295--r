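item_id,instrument,subscale,min_level,max_level,negative_direction
effort_1,ERI_EFFORT,NONE,1,5,1
effort_2,ERI_EFFORT,NONE,1,5,1
effort_3,ERI_EFFORT,NONE,1,5,1
effort_4,ERI_EFFORT,NONE,1,5,1
effort_5,ERI_EFFORT,NONE,1,5,1
effort_6,ERI_EFFORT,NONE,1,5,1
esteem_1,ERI_REWARD,ESTEEM,1,5,-1
esteem_2,ERI_REWARD,ESTEEM,1,5,-1
esteem_3,ERI_REWARD,ESTEEM,1,5,-1
esteem_4,ERI_REWARD,ESTEEM,1,5,-1
esteem_5,ERI_REWARD,ESTEEM,1,5,-1
promotion_1,ERI_REWARD,PROMOTION,1,5,-1
promotion_2,ERI_REWARD,PROMOTION,1,5,-1
promotion_3,ERI_REWARD,PROMOTION,1,5,-1
promotion_4,ERI_REWARD,PROMOTION,1,5,-1
security_1,ERI_REWARD,SECURITY,1,5,-1
security_2,ERI_REWARD,SECURITY,1,5,-1
ghq_1,GHQ,NONE,0,3,1
ghq_2,GHQ,NONE,0,3,1
ghq_3,GHQ,NONE,0,3,1
ghq_4,GHQ,NONE,0,3,1
ghq_5,GHQ,NONE,0,3,1
ghq_6,GHQ,NONE,0,3,1
ghq_7,GHQ,NONE,0,3,1
ghq_8,GHQ,NONE,0,3,1
ghq_9,GHQ,NONE,0,3,1
ghq_10,GHQ,NONE,0,3,1
ghq_11,GHQ,NONE,0,3,1
ghq_12,GHQ,NONE,0,3,1
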