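[
  {"item_id": "art_sleep_01", "kind": "article", "domains": ["sleep"], "title": "Sleep hygiene after a cardiac event"},
  {"item_id": "lay_sleep_02", "kind": "lay_summary", "domains": ["sleep", "mood"], "title": "How poor sleep and low mood feed each other"},
  {"item_id": "vid_mood_01", "kind": "video", "domains": ["mood"], "title": "Managing low mood with cardiac pain"},
  {"item_id": "pod_mood_02", "kind": "podcast", "domains": ["mood", "relations"], "title": "Talking to loved ones about your heart"},
  {"item_id": "art_walk_01", "kind": "article", "domains": ["walking", "general_activities"], "title": "Safe walking plans for angina"},
  {"item_id": "lay_work_01", "kind": "lay_summary", "domains": ["work"], "title": "Returning to paid and unpaid work"},
  {"item_id": "vid_activity_01", "kind": "video", "domains": ["general_activities"], "title": "Pacing your daily activities"},
  {"item_id": "pod_enjoy_01", "kind": "podcast", "domains": ["enjoyment", "mood"], "title": "Finding enjoyment despite chronic pain"},
  {"item_id": "art_relations_01", "kind": "article", "domains": ["relations"], "title": "Cardiac pain and your relationships"},
  {"item_id": "art_kounis_01", "kind": "article", "domains": ["general_activities"], "title": "Kounis syndrome: allergy and the heart, a lay summary"}
]
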